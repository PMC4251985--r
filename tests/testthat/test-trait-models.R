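star3 <- function() {
  tr <- ape::read.tree(text = "(A:1,B:1,C:1);")
  paint_regimes(tr, c(A = "r", B = "r", C = "r"))
}

test_that("BM likelihood and MLE match closed forms on a star tree", {
  p <- star3()
  y <- c(A = 1, B = 2, C = 3)
  ## independent N(z0, sigma2) tips
  expect_equal(bm_loglik(p, y, z0 = 2, rates = 1.5),
               sum(dnorm(y, 2, sqrt(1.5), log = TRUE)), tolerance = 1e-10)
  f <- fit_bm(p, y)
  expect_equal(f$par$z0, 2, tolerance = 1e-9)
  expect_equal(unname(f$par$sigma2), 2 / 3, tolerance = 1e-9)
  expect_equal(f$logLik, sum(dnorm(y, 2, sqrt(2 / 3), log = TRUE)),
               tolerance = 1e-9)
})

test_that("BM likelihood is invariant to branch/rate rescaling and rate-equality nesting", {
  p <- painted_quartet()
  y <- c(A = 0.3, B = 1.1, C = -0.4, D = 0.9)
  ll1 <- bm_loglik(p, y, 0.2, c(x = 0.8, y = 0.8))
  ## equal two-rate model == single rate
  expect_equal(ll1, bm_loglik(p, y, 0.2, 0.8), tolerance = 1e-12)
  ## scale branches by c, divide rates by c
  tr2 <- p
  tr2$edge.length <- tr2$edge.length * 5
  expect_equal(bm_loglik(tr2, y, 0.2, c(x = 0.16, y = 0.16)), ll1,
               tolerance = 1e-9)
})

test_that("BM likelihood and MLE agree with independent-contrasts computations", {
  for (seed in 1:3) {
    set.seed(seed)
    tr <- ape::rcoal(8)
    tr <- rescale_tree_height(tr)
    p <- paint_regimes(tr, setNames(rep("r", 8), tr$tip.label))
    y <- setNames(rnorm(8, 5, 1), tr$tip.label)
    ## direct MVN oracle built from ape's phylogenetic covariance
    s2 <- 0.7
    V <- s2 * ape::vcv(tr)[names(y), names(y)]
    direct <- -0.5 * (length(y) * log(2 * pi) +
                      as.numeric(determinant(V)$modulus) +
                      drop(t(y - 5) %*% solve(V, y - 5)))
    expect_equal(bm_loglik(p, y, 5, s2), direct, tolerance = 1e-6)
    ## ML rate oracle: the sum of squared scaled contrasts is the GLS
    ## quadratic form, so sigma2_ML = sum(pic^2) / n
    pic <- ape::pic(y, tr)
    f <- fit_bm(p, y)
    expect_equal(unname(f$par$sigma2), sum(pic^2) / length(y),
                 tolerance = 1e-6)
  }
})

test_that("two-rate BM fits match the brownie reference implementation", {
  skip_if_not_installed("phytools")
  set.seed(9)
  tr <- ape::rcoal(12)
  tr <- rescale_tree_height(tr)
  regs <- setNames(rep(c("a", "b"), each = 6), tr$tip.label)
  p <- paint_regimes(tr, regs, interior_rule = "parsimony",
                     root_regime = "a")
  y <- simulate_trait(p, list(family = "BM", z0 = 0,
                              sigma2 = c(a = 1, b = 6)), seed = 4)
  f <- fit_trait_model(p, y, "BM2")
  ## reference: phytools::brownie.lite on a simmap tree painted edge-by-edge
  ## to match our painting exactly
  reg_edges <- regimes(p)
  sm <- phytools::paintBranches(tr, edge = tr$edge[reg_edges == "b", 2],
                                state = "b", anc.state = "a")
  ref <- phytools::brownie.lite(sm, y)
  expect_equal(f$logLik, ref$logL.multiple, tolerance = 1e-3)
  expect_equal(sort(unname(f$par$sigma2)),
               sort(unname(ref$sig2.multiple)), tolerance = 0.02)
  ## single-rate logL agrees too
  f1 <- fit_trait_model(p, y, "BM1")
  expect_equal(f1$logLik, ref$logL1, tolerance = 1e-3)
})

test_that("OU likelihood limits: BM as alpha -> 0, stationary independence for large alpha", {
  for (seed in 1:3) {
    set.seed(seed)
    tr <- ape::rcoal(10)
    tr <- rescale_tree_height(tr)
    p <- paint_regimes(tr, setNames(rep("r", 10), tr$tip.label))
    y <- setNames(rnorm(10, 1, 0.5), tr$tip.label)
    expect_lt(abs(ou_loglik(p, y, alpha = 1e-6, sigma2 = 0.8,
                            optima = c(r = 0.4)) -
                  bm_loglik(p, y, z0 = 0.4, rates = 0.8)), 1e-3)
  }
  ## large alpha*T: tips approx independent N(theta, sigma2 / (2 alpha));
  ## checked on a quartet whose smallest patristic distance is 1, so the
  ## between-tip covariance e^{-alpha d} really has died out
  q <- painted_quartet()
  yq <- c(A = 0.9, B = 1.2, C = 1.05, D = 0.7)
  a <- 30
  ll <- ou_loglik(q, yq, alpha = a, sigma2 = 2,
                  optima = c(x = 1, y = 1))
  expect_equal(ll, sum(dnorm(yq, 1, sqrt(2 / (2 * a)), log = TRUE)),
               tolerance = 1e-6)
})

test_that("OU likelihood is invariant to relabeling regimes with their optima", {
  tr <- ape::read.tree(text = "((A:0.5,B:0.5):0.5,(C:0.5,D:0.5):0.5);")
  p <- paint_regimes(tr, c(A = "x", B = "x", C = "y", D = "y"),
                     root_regime = "x")
  y <- c(A = 0.2, B = 0.5, C = 1.4, D = 1.8)
  ll <- ou_loglik(p, y, 2, 1, c(x = 0, y = 1.5))
  ## swap regime names together with optima (root regime follows the swap)
  p2 <- paint_regimes(tr, c(A = "y", B = "y", C = "x", D = "x"),
                      root_regime = "y")
  ll2 <- ou_loglik(p2, y, 2, 1, c(y = 0, x = 1.5))
  expect_equal(ll2, ll, tolerance = 1e-12)
})

test_that("nested maxima ordering holds across model families", {
  p <- painted_study_tree()
  for (seed in 1:4) {
    y <- simulate_trait(p, ou3_truth(), seed = seed)
    fits <- lapply(setNames(nm = c("BM1", "BM2", "OU1", "OU2", "OU3")),
                   function(m) fit_trait_model(p, y, m)$logLik)
    expect_gte(fits$BM2, fits$BM1 - 1e-6)
    expect_gte(fits$OU2, fits$OU1 - 1e-6)
    expect_gte(fits$OU3, fits$OU2 - 1e-6)
  }
  ## OU3 with all three optima constrained equal reproduces OU1
  y <- simulate_trait(p, ou3_truth(), seed = 9)
  f1 <- fit_trait_model(p, y, "OU1")
  f3c <- fit_trait_model(p, y, "OU3",
                         groups = c(JS = "g", PO_anad = "g", PO_fresh = "g"))
  ## same single-group structure -> same profile
  expect_equal(f3c$logLik, f1$logLik, tolerance = 1e-6)
})

test_that("degenerate structures are rejected, not silently collapsed", {
  p <- painted_quartet()
  y <- c(A = 0.3, B = 1.1, C = -0.4, D = 0.9)
  ## more groups than the model admits
  expect_error(fit_trait_model(p, y, "BM1",
                               groups = c(x = "g1", y = "g2")),
               "at most 1 parameter group")
  ## a rate group whose regimes own no branch: paint the root with a regime
  ## that appears nowhere on the tree
  tr <- ape::read.tree(text = "((A:0.5,B:0.5):0.5,(C:0.5,D:0.5):0.5);")
  pq <- paint_regimes(tr, c(A = "r", B = "r", C = "r", D = "r"),
                      interior_rule = "stem", root_regime = "q")
  expect_error(fit_trait_model(pq, y, "BM2",
                               groups = c(r = "g1", q = "g2")),
               "degenerate parameter group")
  ## BM2 on a tree where one regime spans a single terminal branch converges
  p1 <- paint_regimes(tr, c(A = "solo", B = "rest", C = "rest", D = "rest"),
                      root_regime = "rest")
  f <- fit_trait_model(p1, y, "BM2")
  expect_true(is.finite(f$logLik))
  expect_true(all(f$par$sigma2 > 0))
})

test_that("trait simulation is seeded, matches moments, and handles sigma2 = 0", {
  p <- painted_quartet()
  s1 <- simulate_trait(p, list(family = "BM", z0 = 1, sigma2 = 0.5), seed = 7)
  s2 <- simulate_trait(p, list(family = "BM", z0 = 1, sigma2 = 0.5), seed = 7)
  expect_identical(s1, s2)
  ## zero rate -> all tips at root state
  s0 <- simulate_trait(p, list(family = "BM", z0 = 3.3, sigma2 = 0), seed = 1)
  expect_true(all(s0 == 3.3))

  ## OU moment oracle on a 2-tip tree
  tr2 <- ape::read.tree(text = "(A:1,B:1);")
  p2 <- paint_regimes(tr2, c(A = "r", B = "r"))
  alpha <- 1.2; s2v <- 2; th <- 5; z0 <- 1
  sims <- simulate_trait(p2, list(family = "OU", alpha = alpha, sigma2 = s2v,
                                  theta = c(r = th), z0 = z0),
                         seed = 11, nsim = 10000)
  m_theory <- z0 * exp(-alpha) + th * (1 - exp(-alpha))
  v_theory <- s2v * (1 - exp(-2 * alpha)) / (2 * alpha)
  se_m <- sqrt(v_theory / 10000)
  expect_lt(abs(mean(sims["A", ]) - m_theory), 3 * se_m)
  expect_lt(abs(var(sims["A", ]) - v_theory),
            3 * v_theory * sqrt(2 / 9999))
  ## tips are independent on a star: correlation near zero
  expect_lt(abs(cor(sims["A", ], sims["B", ])), 0.05)
})

test_that("simulated BM1 data give balanced BM2 rate estimates (recovery)", {
  p <- painted_study_tree()
  ok <- 0L
  n_trials <- 50L
  for (i in seq_len(n_trials)) {
    y <- simulate_trait(p, list(family = "BM", z0 = 0,
                                sigma2 = c(JS = 1, PO_anad = 1, PO_fresh = 1)),
                        seed = 1000 + i)
    f <- fit_trait_model(p, y, "BM2")
    rr <- unname(f$par$sigma2)
    if (max(rr) / min(rr) < 2) ok <- ok + 1L
  }
  ## both rates within 2x of each other in most replicates under equal-rate truth
  expect_gte(ok / n_trials, 0.6)
})

test_that("sigma2 estimates under BM1 are nearly unbiased on the study tree", {
  p <- painted_study_tree()
  est <- vapply(1:500, function(i) {
    y <- simulate_trait(p, list(family = "BM", z0 = 0, sigma2 = 2),
                        seed = 5000 + i)
    unname(fit_trait_model(p, y, "BM1")$par$sigma2)
  }, numeric(1))
  expect_lt(abs(mean(est) - 2) / 2, 0.15)
})

test_that("parametric-bootstrap CIs behave sensibly", {
  p <- painted_study_tree()
  y <- simulate_trait(p, ou3_truth(), seed = 21)
  f <- fit_trait_model(p, y, "BM2")
  fc <- bootstrap_ci(f, n_reps = 60, seed = 2)
  expect_true(all(fc$ci$lower <= fc$ci$estimate + 1e-9))
  expect_true(all(fc$ci$upper >= fc$ci$estimate - 1e-9))
  expect_false(fc$ci_meta$flagged)
  ## n_reps = 1 -> degenerate, flagged
  expect_warning(f1 <- bootstrap_ci(f, n_reps = 1, seed = 2), "degenerate")
  expect_true(f1$ci_meta$flagged)
})

test_that("bootstrap CI coverage of a BM rate is near nominal", {
  ## 100 synthetic datasets on the 24-tip study tree, 200-replicate
  ## percentile intervals: coverage of the true rate should sit near 95%
  p <- painted_study_tree()
  truth <- 1.5
  hits <- 0L
  n_data <- 100L
  for (i in seq_len(n_data)) {
    y <- simulate_trait(p, list(family = "BM", z0 = 0, sigma2 = truth),
                        seed = 300 + i)
    f <- fit_trait_model(p, y, "BM1")
    fc <- bootstrap_ci(f, n_reps = 200, seed = i)
    if (fc$ci["sigma2.all", "lower"] <= truth &&
        fc$ci["sigma2.all", "upper"] >= truth) hits <- hits + 1L
  }
  ## target band for the true coverage is [88%, 99%]; with 100 datasets the
  ## estimate carries binomial noise (SE ~ 3%), so the lower edge is tested
  ## with a 3-SE Monte-Carlo allowance
  expect_gte(hits / n_data, 0.88 - 3 * sqrt(0.9 * 0.1 / n_data))
  expect_lte(hits / n_data, 0.99)
})

test_that("fit methods expose coherent coefficients, predictions and residuals", {
  p <- painted_study_tree()
  y <- simulate_trait(p, ou3_truth(), seed = 3)
  f <- fit_trait_model(p, y, "OU3")
  expect_named(coef(f), c("alpha", "sigma2", "theta.JS", "theta.PO_anad",
                          "theta.PO_fresh"))
  expect_equal(as.numeric(logLik(f)), f$logLik)
  expect_equal(attr(logLik(f), "df"), 5L)
  mu <- predict(f)
  expect_equal(names(mu), f$td$tips)
  expect_equal(residuals(f), y[f$td$tips] - mu)
  expect_output(print(f), "OU3 trait-evolution")
  expect_output(print(summary(f)), "Coefficients")
  ## simulate method round-trips through the generic
  s <- simulate(f, nsim = 3, seed = 5)
  expect_equal(dim(s), c(24L, 3L))
  ## JSON serialization carries the estimates
  path <- withr::local_tempfile(fileext = ".json")
  write_trait_fit(f, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$model, "OU3")
  expect_equal(back$logLik, f$logLik, tolerance = 1e-12)
  expect_equal(unlist(back$coef), coef(f), tolerance = 1e-12)
})
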