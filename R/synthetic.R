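#' Synthetic study scenario configuration
#'
#' Bundles every parameter of the synthetic data generator. Defaults emulate
#' the study design the package targets: 24 populations in two monophyletic
#' clades — a Japan Sea clade (regime \code{JS}) and a Pacific Ocean clade
#' containing a nested freshwater sub-group (\code{PO_anad}, \code{PO_fresh})
#' — genotyped at 10 unlinked microsatellite loci evolving under a symmetric
#' single-step stepwise mutation model in Wright-Fisher populations, with
#' gill-raker-like traits evolving under a three-optimum OU model (optima
#' 24.5 / 21.75 / 18.0), two-source isotope mixtures (marine vs freshwater
#' benthic), multinomial stomach contents and count-valued foraging trials.
#'
#' @param n_js,n_po,n_pf Number of Japan Sea anadromous, Pacific Ocean
#'   anadromous and Pacific Ocean freshwater populations.
#' @param sample_size Diploid individuals sampled per population.
#' @param n_loci Number of microsatellite loci.
#' @param mu Mutation rate per allele copy per generation.
#' @param ne Effective population size (diploid) along every branch.
#' @param t_root,t_clade,t_pf Split times in generations: root split between
#'   clades, span of the within-clade splits, and the stem age of the
#'   freshwater sub-group.
#' @param founder_allele Founder allele size in repeat units.
#' @param burn_in Root burn-in generations (default \code{8 * ne}, enough to
#'   reach mutation-drift equilibrium so divergence is linear in time).
#' @param trait_model Trait truth: list with \code{family} (\code{"OU"} or
#'   \code{"BM"}) and its parameters, named by regime where per-regime.
#' @param isotope Isotope truth: source means/SDs and per-form contribution
#'   simplexes, consumer n and residual SD.
#' @param diet Per-form multinomial prey-category profiles and items per
#'   stomach.
#' @param foraging Per-form Poisson strike rates and binomial consumption
#'   probabilities for the trial generator.
#' @return A list of class \code{scenario_config}.
#' @export
scenario_config <- function(n_js = 8L, n_po = 10L, n_pf = 6L,
                            sample_size = 10L, n_loci = 10L,
                            mu = 5e-4, ne = 500L,
                            t_root = 1000, t_clade = 300, t_pf = 200,
                            founder_allele = 20L, burn_in = NULL,
                            trait_model = NULL, isotope = NULL,
                            diet = NULL, foraging = NULL) {
  if (ne < sample_size) stop("effective size below the sample size")
  stopifnot(mu >= 0, t_root > t_clade, t_clade > 0)
  if (is.null(burn_in)) burn_in <- 8L * ne
  if (is.null(trait_model)) {
    ## alpha*T = 8 and stationary SD 1 put simulated population means tightly
    ## around their optima, matching the clustering of the observed trait
    ## tables this scenario emulates
    trait_model <- list(
      family = "OU", alpha = 8, sigma2 = 16,
      theta = c(JS = 24.5, PO_anad = 21.75, PO_fresh = 18.0))
  }
  if (is.null(isotope)) {
    isotope <- list(
      sources = data.frame(
        name = c("marine_benthic", "freshwater_benthic"),
        mean_d13C = c(-16, -26), sd_d13C = c(1, 1),
        mean_d15N = c(10, 6), sd_d15N = c(1, 1),
        stringsAsFactors = FALSE),
      contributions = list(JS = c(0.8, 0.2), PO_anad = c(0.45, 0.55),
                           PO_fresh = c(0.1, 0.9)),
      frac = c(d13C = 0.39, d15N = 3.4),
      frac_sd = c(d13C = 1.3, d15N = 0.98),
      n_consumers = 20L, resid_sd = 0.5)
  }
  if (is.null(diet)) {
    categories <- c("terrestrial_insects", "zooplankton",
                    "benthic_macroinvertebrates", "fish", "fish_eggs",
                    "plant_material", "other")
    diet <- list(
      categories = categories,
      profiles = list(
        JS = c(0.05, 0.7, 0.1, 0.02, 0.03, 0.05, 0.05),
        PO_anad = c(0.1, 0.05, 0.6, 0.05, 0.05, 0.05, 0.1),
        PO_fresh = c(0.15, 0.05, 0.6, 0.02, 0.03, 0.05, 0.1)),
      items_per_stomach = 12, mean_item_weight = 2,
      n_fish = 20L)
  }
  if (is.null(foraging)) {
    foraging <- list(
      strike_lambda_v = c(JS = 25, PO_anad = 35, PO_fresh = 35),
      strike_lambda_h = c(JS = 12, PO_anad = 8, PO_fresh = 8),
      p_consume = c(JS = 0.3, PO_anad = 0.7, PO_fresh = 0.7),
      length_mean = c(JS = 53.6, PO_anad = 68.2, PO_fresh = 60),
      length_sd = 3, n_trials = 20L, duration = 600)
  }
  structure(
    list(n_js = n_js, n_po = n_po, n_pf = n_pf, sample_size = sample_size,
         n_loci = n_loci, mu = mu, ne = ne, burn_in = burn_in,
         t_root = t_root, t_clade = t_clade, t_pf = t_pf,
         founder_allele = founder_allele,
         trait_model = trait_model, isotope = isotope, diet = diet,
         foraging = foraging),
    class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("Synthetic scenario: %d populations (%d JS / %d PO / %d PF)\n",
              x$n_js + x$n_po + x$n_pf, x$n_js, x$n_po, x$n_pf))
  cat(sprintf("  %d loci, mu = %g, Ne = %d, root split %g generations\n",
              x$n_loci, x$mu, x$ne, x$t_root))
  cat(sprintf("  trait truth: %s\n", x$trait_model$family))
  invisible(x)
}

#' True population tree of a scenario
#'
#' Builds the generating population tree (branch lengths in generations):
#' two clades splitting at \code{t_root}; ladder-shaped within-clade splits
#' spread up to \code{t_clade} ago; and each freshwater population attached
#' as a recent sister (age \code{t_pf}) of a Pacific Ocean anadromous
#' population — freshwater colonisation is repeated within the clade, not a
#' single event, mirroring the repeated marine-to-freshwater transitions the
#' scenario emulates.
#'
#' @param cfg A \code{\link{scenario_config}} (requires
#'   \code{n_pf <= n_po}).
#' @return A rooted ultrametric \code{phylo}; tip labels \code{JS1..},
#'   \code{PO1..}, \code{PF1..}. The matching tip regime map is attached as
#'   attribute \code{tip_regimes}.
#' @export
scenario_tree <- function(cfg) {
  ## comb over newick fragments with given heights, joined at given times
  ladder <- function(frags, heights, times) {
    nwk <- frags[1]
    h <- heights[1]
    for (i in seq_along(times)) {
      t_i <- times[i]
      nwk <- sprintf("(%s:%.8g,%s:%.8g)", nwk, t_i - h,
                     frags[i + 1L], t_i - heights[i + 1L])
      h <- t_i
    }
    nwk
  }
  if (cfg$n_js < 1L || cfg$n_po < 1L) stop("need at least one JS and one PO population")
  if (cfg$n_pf > cfg$n_po) stop("need n_pf <= n_po (each freshwater population descends from an anadromous one)")
  js <- paste0("JS", seq_len(cfg$n_js))
  po <- paste0("PO", seq_len(cfg$n_po))
  pf <- if (cfg$n_pf > 0L) paste0("PF", seq_len(cfg$n_pf)) else character(0)
  js_nwk <- ladder(js, rep(0, cfg$n_js),
                   if (cfg$n_js > 1L)
                     seq(cfg$t_clade / cfg$n_js, cfg$t_clade,
                         length.out = cfg$n_js)[-1] else numeric(0))
  js_h <- if (cfg$n_js > 1L) cfg$t_clade else 0
  ## PO fragments: the first n_pf carry a freshwater sister of age t_pf
  frags <- character(cfg$n_po)
  heights <- numeric(cfg$n_po)
  for (i in seq_len(cfg$n_po)) {
    if (i <= cfg$n_pf) {
      frags[i] <- sprintf("(%s:%.8g,%s:%.8g)", po[i], cfg$t_pf, pf[i],
                          cfg$t_pf)
      heights[i] <- cfg$t_pf
    } else {
      frags[i] <- po[i]
    }
  }
  po_lo <- if (cfg$n_pf > 0L) {
    max(cfg$t_pf * 1.2, 0.95 * cfg$t_clade / cfg$n_po)
  } else {
    0.95 * cfg$t_clade / cfg$n_po
  }
  po_times <- if (cfg$n_po > 1L)
    seq(po_lo, 0.95 * cfg$t_clade, length.out = cfg$n_po)[-1] else numeric(0)
  po_nwk <- ladder(frags, heights, po_times)
  po_h <- if (cfg$n_po > 1L) 0.95 * cfg$t_clade else heights[1]
  nwk <- sprintf("(%s:%.8g,%s:%.8g);",
                 js_nwk, cfg$t_root - js_h,
                 po_nwk, cfg$t_root - po_h)
  tree <- ape::read.tree(text = nwk)
  attr(tree, "tip_regimes") <- stats::setNames(
    c(rep("JS", cfg$n_js), rep("PO_anad", cfg$n_po), rep("PO_fresh", cfg$n_pf)),
    c(js, po, pf))
  tree
}

## one Wright-Fisher + stepwise-mutation generation for a 2Ne x L allele pool
wf_generation <- function(pool, mu) {
  nn <- nrow(pool)
  L <- ncol(pool)
  idx <- sample.int(nn, nn * L, replace = TRUE) + rep((seq_len(L) - 1L) * nn,
                                                      each = nn)
  pool <- matrix(pool[idx], nn, L)
  if (mu > 0) {
    hit <- stats::runif(nn * L) < mu
    n_hit <- sum(hit)
    if (n_hit) {
      pool[hit] <- pool[hit] + sample(c(-1L, 1L), n_hit, replace = TRUE)
    }
  }
  pool
}

evolve_pool <- function(pool, generations, mu) {
  g <- 0L
  while (g < generations) {
    pool <- wf_generation(pool, mu)
    g <- g + 1L
  }
  pool
}

#' Simulate microsatellite genotypes down a population tree
#'
#' Forward Wright-Fisher simulation with a symmetric single-step stepwise
#' mutation model: a pool of \code{2 Ne} allele copies per locus starts at the
#' founder allele, burns in to mutation-drift equilibrium along the root stem,
#' is copied at every split, evolves independently down each branch
#' (resampling \code{2 Ne} copies each generation, mutating each copy +/- 1
#' repeat unit at rate \code{mu}), and is sampled at the tips for the
#' requested number of diploids. Under this model the expected squared
#' difference in mean allele size between two populations split t generations
#' ago is \code{2 * mu * t}.
#'
#' @param cfg A \code{\link{scenario_config}}.
#' @param seed Integer seed (fully determines the output).
#' @param tree Population tree with branch lengths in generations; defaults to
#'   \code{\link{scenario_tree}(cfg)}.
#' @return A \code{\link{genotype_table}} (repeat lengths drawn from 2/3/4 bp
#'   motifs so the base-pair CSV round-trip is exercised).
#' @export
simulate_genotypes <- function(cfg, seed = 1L, tree = NULL) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (cfg$ne < cfg$sample_size) stop("effective size below the sample size")
  if (is.null(tree)) tree <- scenario_tree(cfg)
  n_tip <- length(tree$tip.label)
  nn2 <- 2L * cfg$ne
  with_seed(seed, {
    pool0 <- matrix(cfg$founder_allele, nn2, cfg$n_loci)
    pool0 <- evolve_pool(pool0, cfg$burn_in, cfg$mu)
    root <- n_tip + 1L
    pools <- vector("list", n_tip + tree$Nnode)
    pools[[root]] <- pool0
    pre <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(pre$edge))) {
      p <- pre$edge[e, 1]; ch <- pre$edge[e, 2]
      pools[[ch]] <- evolve_pool(pools[[p]], round(pre$edge.length[e]), cfg$mu)
    }
    ## sample diploids at the tips
    calls <- vector("list", n_tip)
    loci_names <- sprintf("L%02d", seq_len(cfg$n_loci))
    for (tip in seq_len(n_tip)) {
      pop <- tree$tip.label[tip]
      pool <- pools[[tip]]
      rows <- lapply(seq_len(cfg$n_loci), function(l) {
        picks <- sample.int(nn2, 2L * cfg$sample_size)
        a <- pool[picks, l]
        data.frame(
          population = pop,
          individual = sprintf("%s_i%02d", pop, seq_len(cfg$sample_size)),
          locus = loci_names[l],
          a1 = a[seq_len(cfg$sample_size)],
          a2 = a[cfg$sample_size + seq_len(cfg$sample_size)],
          stringsAsFactors = FALSE)
      })
      calls[[tip]] <- do.call(rbind, rows)
    }
    loci <- data.frame(locus = loci_names,
                       repeat_length = rep_len(c(2L, 3L, 4L), cfg$n_loci),
                       stringsAsFactors = FALSE)
    genotype_table(do.call(rbind, calls), loci)
  })
}

#' Simulate the ecological data of a scenario
#'
#' Generates every non-genetic input of the analysis under the scenario's
#' declared truth: tip traits by \code{\link{simulate_trait}} on the
#' regime-painted true tree (rescaled to unit height), per-individual consumer
#' isotopes drawn from the true source mixture (mixture-weighted mean, and
#' variance propagated from source, fractionation and residual SDs),
#' multinomial stomach contents from form-specific prey profiles, and foraging
#' trials with Poisson strikes and binomial consumptions.
#'
#' @param cfg A \code{\link{scenario_config}}.
#' @param seed Integer seed.
#' @param tree Optional population tree (defaults to the scenario tree).
#' @return List with elements \code{traits} (named vector), \code{tree}
#'   (painted, unit height), \code{isotopes}, \code{sources}, \code{diet},
#'   \code{trials} (data frames) and \code{truth} (the generating parameters).
#' @export
simulate_ecology <- function(cfg, seed = 1L, tree = NULL) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (is.null(tree)) tree <- scenario_tree(cfg)
  tip_regimes <- attr(tree, "tip_regimes")
  painted <- paint_regimes(rescale_tree_height(tree), tip_regimes,
                           interior_rule = "parsimony",
                           root_regime = if (any(tip_regimes == "PO_anad"))
                             "PO_anad" else NULL)
  tm <- cfg$trait_model
  params <- if (tm$family == "OU") {
    list(family = "OU", alpha = tm$alpha, sigma2 = tm$sigma2, theta = tm$theta)
  } else {
    list(family = "BM", z0 = tm$z0, sigma2 = tm$sigma2)
  }
  traits <- simulate_trait(painted, params, seed = child_seed(seed, 1L))
  iso <- cfg$isotope
  forms <- names(iso$contributions)
  frac <- iso$frac %||% c(d13C = 0.39, d15N = 3.4)
  frac_sd <- iso$frac_sd %||% c(d13C = 1.3, d15N = 0.98)
  isotopes <- with_seed(child_seed(seed, 2L), {
    do.call(rbind, lapply(forms, function(fm) {
      p <- iso$contributions[[fm]]
      mu_c <- sum(p * (iso$sources$mean_d13C + frac[["d13C"]]))
      mu_n <- sum(p * (iso$sources$mean_d15N + frac[["d15N"]]))
      v_c <- sum(p^2 * (iso$sources$sd_d13C^2 + frac_sd[["d13C"]]^2)) +
        iso$resid_sd^2
      v_n <- sum(p^2 * (iso$sources$sd_d15N^2 + frac_sd[["d15N"]]^2)) +
        iso$resid_sd^2
      n <- iso$n_consumers
      data.frame(
        individual = sprintf("%s_c%03d", fm, seq_len(n)), group = fm,
        d13C = stats::rnorm(n, mu_c, sqrt(v_c)),
        d15N = stats::rnorm(n, mu_n, sqrt(v_n)),
        C_N = stats::runif(n, 3.2, 4.5),
        lipid_normalized = TRUE,
        stringsAsFactors = FALSE)
    }))
  })
  dt <- cfg$diet
  diet <- with_seed(child_seed(seed, 3L), {
    do.call(rbind, lapply(names(dt$profiles), function(fm) {
      do.call(rbind, lapply(seq_len(dt$n_fish), function(i) {
        counts <- stats::rmultinom(1, dt$items_per_stomach, dt$profiles[[fm]])[, 1]
        data.frame(
          fish = sprintf("%s_f%03d", fm, i), group = fm,
          category = dt$categories, count = as.integer(counts),
          weight = counts * stats::rgamma(length(counts),
                                          shape = 4,
                                          rate = 4 / dt$mean_item_weight),
          stringsAsFactors = FALSE)
      }))
    }))
  })
  fo <- cfg$foraging
  trials <- with_seed(child_seed(seed, 4L), {
    do.call(rbind, lapply(names(fo$strike_lambda_v), function(fm) {
      n <- fo$n_trials
      s_v <- stats::rpois(n, fo$strike_lambda_v[[fm]])
      s_h <- stats::rpois(n, fo$strike_lambda_h[[fm]])
      handled <- stats::rbinom(n, s_v + s_h, 0.8)
      consumed <- stats::rbinom(n, handled, fo$p_consume[[fm]])
      data.frame(
        fish = sprintf("%s_t%03d", fm, seq_len(n)), form = fm,
        standard_length = stats::rnorm(n, fo$length_mean[[fm]], fo$length_sd),
        s_v = s_v, s_h = s_h, handled = handled,
        abandoned = handled - consumed, duration = fo$duration,
        stringsAsFactors = FALSE)
    }))
  })
  list(traits = traits, tree = painted, isotopes = isotopes,
       sources = iso$sources, diet = diet, trials = trials,
       truth = list(trait_model = tm, contributions = iso$contributions,
                    foraging = fo, seed = seed))
}

#' Write a complete scenario directory
#'
#' Emits every input file of the pipeline in its plain-text interchange
#' format: \code{genotypes.csv} + \code{loci.csv} (base-pair alleles and the
#' repeat-length sidecar), \code{traits.csv}, \code{isotopes.csv},
#' \code{sources.csv}, \code{diet.csv}, \code{trials.csv}, the true tree as
#' \code{tree.nwk} and the generating parameters as \code{truth.json}.
#'
#' @param cfg A \code{\link{scenario_config}}.
#' @param dir Output directory (created if needed).
#' @param seed Master seed.
#' @return Invisibly, \code{dir}.
#' @export
write_scenario <- function(cfg, dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tree <- scenario_tree(cfg)
  g <- simulate_genotypes(cfg, seed = child_seed(seed, 101L), tree = tree)
  eco <- simulate_ecology(cfg, seed = child_seed(seed, 102L), tree = tree)
  write_genotypes(g, file.path(dir, "genotypes.csv"),
                  file.path(dir, "loci.csv"))
  utils::write.csv(
    data.frame(population = names(eco$traits),
               gill_raker = as.numeric(eco$traits)),
    file.path(dir, "traits.csv"), row.names = FALSE)
  utils::write.csv(eco$isotopes, file.path(dir, "isotopes.csv"),
                   row.names = FALSE)
  utils::write.csv(eco$sources, file.path(dir, "sources.csv"),
                   row.names = FALSE)
  utils::write.csv(eco$diet, file.path(dir, "diet.csv"), row.names = FALSE)
  utils::write.csv(eco$trials, file.path(dir, "trials.csv"), row.names = FALSE)
  ape::write.tree(tree, file.path(dir, "tree.nwk"))
  tip_regimes <- attr(tree, "tip_regimes")
  utils::write.csv(
    data.frame(population = names(tip_regimes), regime = tip_regimes),
    file.path(dir, "regimes.csv"), row.names = FALSE)
  truth <- list(seed = seed, trait_model = cfg$trait_model,
                contributions = cfg$isotope$contributions,
                mu = cfg$mu, ne = cfg$ne,
                split_times = list(root = cfg$t_root, clade = cfg$t_clade,
                                   pf = cfg$t_pf))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
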