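lab_matrix <- function(v, labs) matrix(v, length(labs), length(labs),
                                       dimnames = list(labs, labs))

test_that("UPGMA reproduces hand-run average linkage and stays ultrametric", {
  d <- lab_matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), c("A", "B", "C"))
  tr <- upgma(d)
  expect_equal(ape::write.tree(tr), "((A:1,B:1):1,C:2);")

  ## two taxa
  d2 <- lab_matrix(c(0, 3, 3, 0), c("A", "B"))
  expect_equal(ape::write.tree(upgma(d2)), "(A:1.5,B:1.5);")

  ## ultrametricity on a random matrix
  set.seed(1)
  n <- 8
  m <- matrix(runif(n * n, 1, 5), n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(letters[1:n], letters[1:n])
  tr3 <- upgma(m)
  depths <- ape::node.depth.edgelength(tr3)[1:n]
  expect_lt(diff(range(depths)), 1e-9)

  expect_error(upgma(lab_matrix(c(0, 1, 2, 0), c("A", "B"))), "symmetric")
  expect_error(upgma(lab_matrix(c(0, Inf, Inf, 0), c("A", "B"))),
               "non-finite")
})

test_that("UPGMA matches the standard average-linkage implementation on random inputs", {
  skip_if_not_installed("phangorn")
  for (seed in 1:3) {
    set.seed(seed)
    n <- 7
    m <- matrix(runif(n * n, 1, 10), n)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    dimnames(m) <- list(paste0("t", 1:n), paste0("t", 1:n))
    ours <- upgma(m)
    ref <- phangorn::upgma(as.dist(m))
    expect_equal(ape::dist.topo(ape::unroot(ours), ape::unroot(ref)), 0,
                 ignore_attr = TRUE)
    ## root-to-tip heights agree too
    expect_equal(sort(ape::node.depth.edgelength(ours)[1:n]),
                 sort(ape::node.depth.edgelength(ref)[1:n]),
                 tolerance = 1e-9)
  }
})

test_that("UPGMA on an exactly ultrametric matrix recovers topology and heights", {
  tr <- ape::read.tree(text = "((A:1,B:1):2,(C:2.5,D:2.5):0.5);")
  d <- ape::cophenetic.phylo(tr)
  rec <- upgma(d)
  expect_equal(ape::dist.topo(ape::unroot(rec), ape::unroot(tr)), 0,
               ignore_attr = TRUE)
  expect_equal(ape::cophenetic.phylo(rec)[rownames(d), colnames(d)], d,
               tolerance = 1e-9)
})

test_that("bootstrap support counts clade recovery exactly", {
  main <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  ## all replicates identical -> 100 everywhere
  s <- bootstrap_support(main, rep(list(main), 10))
  expect_true(all(as.numeric(s$node.label) == 100))

  ## clade (A,B) absent in half the replicates -> 50 at that node
  alt <- ape::read.tree(text = "((A:1,C:1):1,(B:1,D:1):1);")
  s2 <- bootstrap_support(main, c(rep(list(main), 5), rep(list(alt), 5)))
  labs <- as.numeric(s2$node.label)
  expect_equal(sort(labs), c(50, 50, 100))  # root always present

  ## random replicates: agree with ape::prop.clades oracle
  set.seed(2)
  reps <- lapply(1:20, function(i) {
    t <- ape::rcoal(6, tip.label = paste0("t", 1:6))
    t
  })
  main6 <- ape::rcoal(6, tip.label = paste0("t", 1:6))
  ours <- as.numeric(bootstrap_support(main6, reps)$node.label)
  oracle <- ape::prop.clades(main6, reps, rooted = TRUE)
  oracle[is.na(oracle)] <- 0
  expect_equal(ours, 100 * oracle / 20)

  expect_error(bootstrap_support(main, list(ape::rcoal(3))),
               "different tip set")
})

test_that("pruning preserves kept root-to-tip heights and is idempotent", {
  tr <- ape::read.tree(text = "(((A:1,B:1):1,C:2):1,(D:1.5,E:1.5):1.5);")
  full <- prune_tree(tr, tr$tip.label)
  expect_equal(ape::write.tree(full), ape::write.tree(tr))

  sub <- prune_tree(tr, c("A", "C", "D"))
  expect_setequal(sub$tip.label, c("A", "C", "D"))
  h_orig <- ape::node.depth.edgelength(tr)[match(c("A", "C", "D"),
                                                 tr$tip.label)]
  h_sub <- ape::node.depth.edgelength(sub)[match(c("A", "C", "D"),
                                                 sub$tip.label)]
  expect_equal(h_sub, h_orig, tolerance = 1e-12)

  ## 3-tip tree kept to 2: path length between kept tips preserved
  tr3 <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  two <- prune_tree(tr3, c("A", "C"))
  expect_equal(unname(ape::cophenetic.phylo(two)["A", "C"]), 4)

  ## nested prunes equal the direct prune
  nested <- prune_tree(prune_tree(tr, c("A", "B", "C", "D")), c("A", "C", "D"))
  expect_equal(ape::write.tree(nested), ape::write.tree(sub))

  expect_error(prune_tree(tr, c("A", "zz")), "unknown tip")
  expect_error(prune_tree(tr, "A"), "at least 2")
})

test_that("regime painting covers every branch and honours both rules", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  ## all one regime
  p1 <- paint_regimes(tr, c(A = "r", B = "r", C = "r", D = "r"))
  expect_true(all(regimes(p1) == "r"))
  expect_equal(attr(p1, "root_regime"), "r")

  ## two sister clades of distinct regimes; root per config
  p2 <- paint_regimes(tr, c(A = "x", B = "x", C = "y", D = "y"),
                      interior_rule = "stem", root_regime = "x")
  reg <- regimes(p2)
  edge_child <- tr$edge[, 2]
  tipname <- function(i) tr$tip.label[i]
  for (e in seq_along(reg)) {
    if (edge_child[e] <= 4) {
      expect_equal(reg[e], c(A = "x", B = "x", C = "y", D = "y")[[tipname(edge_child[e])]])
    }
  }
  expect_equal(attr(p2, "root_regime"), "x")
  ## partition property: one regime per branch, none missing
  expect_equal(length(reg), nrow(tr$edge))
  expect_false(any(is.na(reg)))

  expect_error(paint_regimes(tr, c(A = "x", B = "x", C = "y")), "without regime")
})

test_that("stem rule confines a nested regime to all-descendant branches", {
  ## PF tips nested inside the PO clade
  tr <- ape::read.tree(
    text = "((JS1:3,JS2:3):1,((PO1:2,PO2:2):1,(PF1:1,PF2:1):2):1);")
  tips <- c(JS1 = "JS", JS2 = "JS", PO1 = "PO_anad", PO2 = "PO_anad",
            PF1 = "PO_fresh", PF2 = "PO_fresh")
  p <- paint_regimes(tr, tips, interior_rule = "stem",
                     root_regime = "PO_anad")
  reg <- regimes(p)
  ## oracle: postorder all-descendant check
  for (e in seq_len(nrow(tr$edge))) {
    ch <- tr$edge[e, 2]
    desc <- if (ch <= 6) ch else unlist(lapply(ch, function(n) {
      w <- integer(0)
      stack <- n
      while (length(stack)) {
        top <- stack[1]; stack <- stack[-1]
        kids <- tr$edge[tr$edge[, 1] == top, 2]
        w <- c(w, kids[kids <= 6])
        stack <- c(stack, kids[kids > 6])
      }
      w
    }))
    rr <- unique(tips[tr$tip.label[desc]])
    expected <- if (length(rr) == 1) rr else "PO_anad"
    expect_equal(reg[e], unname(expected))
  }
  ## PF regime appears only on the PF clade's branches
  expect_equal(sum(reg == "PO_fresh"), 3L)
})

test_that("parsimony painting keeps the backbone in the ancestral lineage state", {
  cfg <- scenario_config()
  tree <- scenario_tree(cfg)
  tips <- attr(tree, "tip_regimes")
  p <- paint_regimes(tree, tips, interior_rule = "parsimony",
                     root_regime = "PO_anad")
  reg <- regimes(p)
  ## every tip edge matches its tip regime
  n <- length(tree$tip.label)
  tip_edges <- which(tree$edge[, 2] <= n)
  expect_equal(unname(reg[tip_edges]),
               unname(tips[tree$tip.label[tree$edge[tip_edges, 2]]]))
  ## all three regimes are present on interior branches of the painted tree
  expect_setequal(unique(reg), c("JS", "PO_anad", "PO_fresh"))
})

test_that("height rescaling floors zero-length terminals and preserves regimes", {
  tr <- ape::read.tree(text = "((A:0,B:1):1,C:2);")
  p <- paint_regimes(tr, c(A = "x", B = "x", C = "y"))
  r <- rescale_tree_height(p, 1)
  expect_equal(max(ape::node.depth.edgelength(r)[1:3]), 1, tolerance = 1e-9)
  expect_true(all(r$edge.length[r$edge[, 2] <= 3] >= 1e-8))
  expect_equal(regimes(r), regimes(p))
})
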