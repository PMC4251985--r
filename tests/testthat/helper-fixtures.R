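## shared fixtures, built in code

## tiny two-population genotype table (allele sizes in repeat units)
tiny_genotypes <- function() {
  calls <- data.frame(
    population = rep(c("A", "B"), each = 4),
    individual = c("a1", "a1", "a2", "a2", "b1", "b1", "b2", "b2"),
    locus = rep(c("L1", "L2"), 4),
    a1 = c(10L, 20L, 10L, 21L, 12L, 20L, 12L, 20L),
    a2 = c(10L, 20L, 11L, 21L, 12L, 22L, 13L, 20L),
    stringsAsFactors = FALSE)
  genotype_table(calls, data.frame(locus = c("L1", "L2"),
                                   repeat_length = c(4L, 2L)))
}

## random genotype table, seeded
random_genotypes <- function(n_pops = 3, n_ind = 5, n_loci = 4, seed = 1) {
  withr_seed <- function(code) {
    set.seed(seed); on.exit(set.seed(NULL)); code
  }
  withr_seed({
    pops <- paste0("P", seq_len(n_pops))
    rows <- list()
    for (p in pops) {
      for (i in seq_len(n_ind)) {
        for (l in seq_len(n_loci)) {
          rows[[length(rows) + 1L]] <- data.frame(
            population = p, individual = paste0(p, "_", i),
            locus = paste0("L", l),
            a1 = sample(8:15, 1), a2 = sample(8:15, 1),
            stringsAsFactors = FALSE)
        }
      }
    }
    genotype_table(do.call(rbind, rows),
                   data.frame(locus = paste0("L", seq_len(n_loci)),
                              repeat_length = 3L))
  })
}

## balanced 4-tip regime-painted unit-height tree
painted_quartet <- function() {
  tr <- ape::read.tree(text = "((A:0.5,B:0.5):0.5,(C:0.5,D:0.5):0.5);")
  paint_regimes(tr, c(A = "x", B = "x", C = "y", D = "y"))
}

## 24-tip study-shaped painted tree (two clades, nested freshwater group)
painted_study_tree <- function(seed = 42) {
  cfg <- scenario_config()
  tree <- scenario_tree(cfg)
  painted <- paint_regimes(rescale_tree_height(tree),
                           attr(tree, "tip_regimes"),
                           interior_rule = "parsimony",
                           root_regime = "PO_anad")
  painted
}

## the scenario's declared trait truth
ou3_truth <- function() {
  tm <- scenario_config()$trait_model
  list(family = tm$family, alpha = tm$alpha, sigma2 = tm$sigma2,
       theta = tm$theta)
}
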