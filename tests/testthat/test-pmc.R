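test_that("pmc comparison is deterministic under a seed and permutation-stable", {
  p <- painted_study_tree()
  y <- simulate_trait(p, ou3_truth(), seed = 4)
  r1 <- pmc_compare(p, y, "BM1", "BM2", n_reps = 30, seed = 7)
  r2 <- pmc_compare(p, y, "BM1", "BM2", n_reps = 30, seed = 7)
  expect_identical(r1$null_dist, r2$null_dist)
  expect_identical(r1$test_dist, r2$test_dist)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$power, r2$power)

  ## p and power depend only on the sets, not the replicate order
  perm <- sample(seq_along(r1$null_dist))
  p_perm <- mean(r1$null_dist[perm] >= r1$delta_obs)
  expect_equal(p_perm, r1$p_value)
  q95 <- sort(r1$null_dist)[ceiling(0.95 * length(r1$null_dist))]
  expect_equal(mean(r1$test_dist > q95), r1$power)

  ## summary table and JSON round-trip replay the result
  tab <- pmc_summary(list(r1))
  expect_equal(tab$delta_obs, r1$delta_obs)
  expect_equal(tab$power, r1$power)
  path <- withr::local_tempfile(fileext = ".json")
  write_pmc(r1, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$null_dist, r1$null_dist, tolerance = 1e-12)
  expect_equal(mean(back$null_dist >= back$delta_obs), r1$p_value)
})

test_that("the 95th-percentile rule is calibrated: same-law distributions give ~5% power", {
  ## two independently seeded null LR distributions of the same nested
  ## comparison are samples from one law; the fraction of one exceeding the
  ## other's nearest-rank 95th percentile should sit near 5%. (A literal
  ## same-family comparison has LR identically zero, which is uninformative.)
  p <- painted_study_tree()
  y <- simulate_trait(p, list(family = "BM", z0 = 0, sigma2 = 1), seed = 2)
  r1 <- pmc_compare(p, y, "BM1", "BM2", n_reps = 200, seed = 5)
  r2 <- pmc_compare(p, y, "BM1", "BM2", n_reps = 200, seed = 60)
  q95 <- sort(r1$null_dist)[ceiling(0.95 * length(r1$null_dist))]
  calib <- mean(r2$null_dist > q95)
  expect_gte(calib, 0.01)
  expect_lte(calib, 0.12)
})

test_that("type-I error of the bootstrap test sits near the nominal 5%", {
  ## the BM1-vs-BM2 LR is invariant to affine transforms of the traits, so
  ## under single-rate truth its null distribution does not depend on z0 or
  ## sigma2; one simulated null distribution therefore serves all trials
  p <- painted_study_tree()
  y <- simulate_trait(p, list(family = "BM", z0 = 0, sigma2 = 1), seed = 2)
  r0 <- pmc_compare(p, y, "BM1", "BM2", n_reps = 300, seed = 31)
  obs <- vapply(1:100, function(i) {
    yo <- simulate_trait(p, list(family = "BM", z0 = 0, sigma2 = 1),
                         seed = 7000 + i)
    f0 <- fit_trait_model(p, yo, "BM1")
    f1 <- fit_trait_model(p, yo, "BM2")
    2 * (f1$logLik - f0$logLik)
  }, numeric(1))
  type1 <- mean(vapply(obs, function(d) mean(r0$null_dist >= d),
                       numeric(1)) < 0.05)
  expect_gte(type1, 0.01)
  expect_lte(type1, 0.11)
})

test_that("pmc detects a strong two-lineage rate difference (power simulation)", {
  ## at the full design (50 trials, n_reps = 200) the detection rate of a
  ## 10x rate contrast measures ~0.88; this desk-scale version uses 15
  ## trials, so the threshold allows for binomial noise around that rate
  p <- painted_study_tree()
  detected <- 0L
  n_trials <- 15L
  for (i in seq_len(n_trials)) {
    y <- simulate_trait(p, list(
      family = "BM", z0 = 0,
      sigma2 = c(JS = 0.5, PO_anad = 5, PO_fresh = 5)), seed = 600 + i)
    r <- pmc_compare(p, y, "BM1", "BM2", n_reps = 200, seed = 600 + i)
    if (r$p_value < 0.05) detected <- detected + 1L
  }
  expect_gte(detected / n_trials, 0.6)
})

test_that("staged selection reaches the expected decisions", {
  p <- painted_study_tree()
  ## clear two-rate BM signal
  y <- simulate_trait(p, list(
    family = "BM", z0 = 22,
    sigma2 = c(JS = 0.3, PO_anad = 6, PO_fresh = 6)), seed = 31)
  res <- list(
    pmc_compare(p, y, "BM1", "BM2", n_reps = 60, seed = 1),
    pmc_compare(p, y, "OU1", "OU2", n_reps = 60, seed = 2),
    pmc_compare(p, y, "OU2", "OU3", n_reps = 60, seed = 3))
  dec <- select_best(res)
  expect_s3_class(dec, "model_decision")
  expect_equal(dec$stages$bm$chosen, "BM2")
  expect_length(dec$finalists, 2)
  ## add the cross-family comparison and re-decide
  cross <- pmc_compare(p, y, dec$finalists[1], dec$finalists[2],
                       n_reps = 60, seed = 4)
  dec2 <- select_best(c(res, list(cross)))
  expect_true(dec2$decision %in% c(dec$finalists, "indistinguishable"))

  expect_error(select_best(list()), "empty")
  ## results on different data are refused
  y2 <- y + 1
  other <- pmc_compare(p, y2, "BM1", "BM2", n_reps = 5, seed = 1)
  expect_error(select_best(list(res[[1]], other)), "different data")
})

test_that("indistinguishable verdict appears when the observed LR sits between the bulks", {
  ## construct pmc_result objects directly: selection is a pure function
  fake <- function(null, test, delta, null_dist, test_dist, id = "d") {
    structure(list(null_model = list(model = null),
                   test_model = list(model = test),
                   delta_obs = delta, null_dist = null_dist,
                   test_dist = test_dist,
                   p_value = mean(null_dist >= delta),
                   power = mean(test_dist > sort(null_dist)[ceiling(0.95 * length(null_dist))]),
                   n_reps = length(null_dist), n_fail_null = 0L,
                   n_fail_test = 0L, flagged = FALSE, seed = 1L,
                   data_id = id), class = "pmc_result")
  }
  null_d <- seq(0, 2, length.out = 100)     # bulk below 2
  test_d <- seq(10, 20, length.out = 100)   # bulk above 10
  res <- list(
    fake("BM1", "BM2", delta = 30, null_d, test_d),   # clear BM2
    fake("OU1", "OU2", delta = 30, null_d, test_d),
    fake("OU2", "OU3", delta = 30, null_d, test_d),
    fake("BM2", "OU3", delta = 5, null_d, test_d))    # falls between bulks
  dec <- select_best(res)
  expect_equal(dec$finalists, c("BM2", "OU3"))
  expect_equal(dec$decision, "indistinguishable")

  ## same setup but the observed LR lands inside the test bulk -> test model
  res[[4]] <- fake("BM2", "OU3", delta = 15, null_d, test_d)
  expect_equal(select_best(res)$decision, "OU3")
  ## and inside the null bulk -> null model
  res[[4]] <- fake("BM2", "OU3", delta = 1, null_d, test_d)
  expect_equal(select_best(res)$decision, "BM2")
})

test_that("subsampling robustness reproduces the full fit at full size and is seeded", {
  p <- painted_study_tree()
  tip_regimes <- stats::setNames(
    rep(c("JS", "PO_anad", "PO_fresh"), c(8, 10, 6)), p$tip.label)
  y <- simulate_trait(p, ou3_truth(), seed = 8)
  full_fit <- fit_trait_model(p, y, "BM2")
  n_po <- sum(tip_regimes == "PO_anad")
  tab <- subsample_robustness(p, y, tip_regimes, "PO_anad",
                              k_range = n_po, n_draws = 1, n_reps = 20,
                              seed = 3)
  expect_equal(tab$sigma2.PO, unname(full_fit$par$sigma2["PO"]),
               tolerance = 1e-6)
  tab2 <- subsample_robustness(p, y, tip_regimes, "PO_anad",
                               k_range = c(4, 6), n_draws = 2, n_reps = 10,
                               seed = 11)
  tab3 <- subsample_robustness(p, y, tip_regimes, "PO_anad",
                               k_range = c(4, 6), n_draws = 2, n_reps = 10,
                               seed = 11)
  expect_equal(tab2, tab3)
  expect_equal(nrow(tab2), 4L)
  expect_error(subsample_robustness(p, y, tip_regimes, "PO_anad",
                                    k_range = 1, n_draws = 1), "below 2")
  expect_error(subsample_robustness(p, y, tip_regimes, "PO_anad",
                                    k_range = 99, n_draws = 1), "exceeds")
})
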