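#' Parametric-bootstrap (Monte Carlo) model comparison
#'
#' Compares two trait-evolution models by simulating likelihood-ratio
#' distributions. Both models are fitted to the data; the observed statistic
#' is \eqn{\delta = 2(\log L_{test} - \log L_{null})}. \code{n_reps} datasets
#' are then simulated under the fitted null and under the fitted test model,
#' and both models are refitted to every simulated dataset (same optimiser
#' settings as the original fits), giving a null and a test distribution of
#' \eqn{\delta}. The p-value is the fraction of the null distribution at or
#' above the observed statistic; power is the fraction of the test
#' distribution exceeding the null distribution's 95th percentile
#' (nearest-rank rule), i.e. the separability of the two models on this tree.
#' Refit failures are dropped and counted, never imputed; a failure rate above
#' 10% flags the result.
#'
#' @param tree A regime-painted tree (rescale to unit height for comparable
#'   rates).
#' @param y Named trait vector.
#' @param null,test Model names (\code{"BM1"}, \code{"BM2"}, \code{"OU1"},
#'   \code{"OU2"}, \code{"OU3"}) or lists \code{list(model =, groups =)} when
#'   a non-default regime-to-parameter grouping is needed.
#' @param n_reps Number of simulated datasets per distribution (the reference
#'   analysis used 1000; reduce for desk-scale runs — the count is recorded in
#'   the result).
#' @param seed Integer seed; replicate r uses derived seed \code{seed + r}
#'   (null) and \code{seed + n_reps + r} (test), so results are reproducible
#'   and replayable.
#' @return Object of class \code{pmc_result}: model pair, \code{delta_obs},
#'   \code{null_dist}, \code{test_dist}, \code{p_value}, \code{power},
#'   failure counts, seed and a data fingerprint.
#' @export
pmc_compare <- function(tree, y, null, test, n_reps = 1000L, seed = 1L) {
  td <- if (inherits(tree, "tree_data")) tree else tree_data(tree)
  null <- as_model_spec(null)
  test <- as_model_spec(test)
  fit0 <- fit_trait_model(td, y, null$model, null$groups)
  fit1 <- fit_trait_model(td, y, test$model, test$groups)
  delta_obs <- 2 * (fit1$logLik - fit0$logLik)
  lr_for <- function(ysim) {
    f0 <- tryCatch(fit_trait_model(td, ysim, null$model, null$groups),
                   error = function(e) NULL)
    f1 <- tryCatch(fit_trait_model(td, ysim, test$model, test$groups),
                   error = function(e) NULL)
    if (is.null(f0) || is.null(f1)) return(NA_real_)
    2 * (f1$logLik - f0$logLik)
  }
  sims_null <- simulate_trait(td, fit0, seed = child_seed(seed, 1L),
                              nsim = n_reps)
  sims_test <- simulate_trait(td, fit1, seed = child_seed(seed, n_reps + 1L),
                              nsim = n_reps)
  if (n_reps == 1L) {
    sims_null <- matrix(sims_null, dimnames = list(names(sims_null), NULL))
    sims_test <- matrix(sims_test, dimnames = list(names(sims_test), NULL))
  }
  null_dist <- apply(sims_null, 2, lr_for)
  test_dist <- apply(sims_test, 2, lr_for)
  n_fail_null <- sum(is.na(null_dist))
  n_fail_test <- sum(is.na(test_dist))
  null_dist <- null_dist[!is.na(null_dist)]
  test_dist <- test_dist[!is.na(test_dist)]
  q95 <- nearest_rank_quantile(null_dist, 0.95)
  out <- list(
    null_model = null, test_model = test,
    fit_null = fit0, fit_test = fit1,
    delta_obs = delta_obs,
    null_dist = null_dist, test_dist = test_dist,
    p_value = mean(null_dist >= delta_obs),
    power = mean(test_dist > q95),
    null_q95 = q95,
    n_reps = n_reps, n_fail_null = n_fail_null, n_fail_test = n_fail_test,
    flagged = (n_fail_null + n_fail_test) > 0.1 * 2 * n_reps,
    seed = seed, data_id = data_id(align_traits(td, y)))
  class(out) <- "pmc_result"
  out
}

as_model_spec <- function(m) {
  if (is.character(m)) return(list(model = m, groups = NULL))
  if (is.list(m) && !is.null(m$model)) {
    return(list(model = m$model, groups = m$groups))
  }
  stop("model must be a name or list(model =, groups =)")
}

## nearest-rank empirical quantile: value at index ceiling(p * n)
nearest_rank_quantile <- function(x, p) {
  s <- sort(x)
  s[max(1L, ceiling(p * length(s)))]
}

#' @export
print.pmc_result <- function(x, ...) {
  cat(sprintf("Parametric-bootstrap comparison: %s (null) vs %s (test)\n",
              x$null_model$model, x$test_model$model))
  cat(sprintf("  observed LR delta = %.4f\n", x$delta_obs))
  cat(sprintf("  p = %.4f, power = %.3f (n_reps = %d, failures: %d null / %d test)\n",
              x$p_value, x$power, x$n_reps, x$n_fail_null, x$n_fail_test))
  if (x$flagged) cat("  WARNING: >10% refit failures; interpret with care\n")
  invisible(x)
}

#' Serialize a pmc result to JSON
#'
#' Writes the full null/test distributions plus summary fields, so the
#' decision in \code{\link{select_best}} is replayable from the file.
#'
#' @param x A \code{pmc_result}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_pmc <- function(x, path) {
  stopifnot(inherits(x, "pmc_result"))
  obj <- list(null_model = x$null_model$model, test_model = x$test_model$model,
              delta_obs = x$delta_obs, p_value = x$p_value, power = x$power,
              n_reps = x$n_reps, n_fail_null = x$n_fail_null,
              n_fail_test = x$n_fail_test, seed = x$seed,
              data_id = x$data_id,
              null_dist = x$null_dist, test_dist = x$test_dist)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Summarise parametric-bootstrap comparisons as a table
#'
#' @param results List of \code{pmc_result} objects.
#' @return Data frame with one row per comparison: the model pair, observed
#'   likelihood ratio, p-value, power, and the effective replicate count
#'   after dropping refit failures.
#' @export
pmc_summary <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    stopifnot(inherits(r, "pmc_result"))
    data.frame(null = r$null_model$model, test = r$test_model$model,
               delta_obs = r$delta_obs, p_value = r$p_value,
               power = r$power,
               n_effective = length(r$null_dist) + length(r$test_dist),
               n_reps = r$n_reps, flagged = r$flagged,
               stringsAsFactors = FALSE)
  }))
}

#' Staged model selection from parametric-bootstrap comparisons
#'
#' Applies the staged decision rule: choose within the BM family
#' (single vs separate rates), choose within the OU family (1 then 2 then 3
#' optima), then compare the best-supported BM and OU models. A stage prefers
#' the richer model when the bootstrap p-value is below \code{alpha_level}.
#' The final cross-family stage reports \code{"indistinguishable"} when the
#' observed likelihood ratio falls between the bulks of the null and test
#' distributions (above the null's 95th percentile but below the test's 5th),
#' or when the two bulks overlap around it — the situation where even high
#' power cannot separate the finalists.
#'
#' @param results List of \code{pmc_result} objects on the same data. The
#'   within-family stages are recognised by their model names (BM1 vs BM2,
#'   OU1 vs OU2, OU2 vs OU3); a cross-family result whose pair matches the two
#'   finalists drives the last stage.
#' @param alpha_level Significance threshold for within-family stages.
#' @return A list of class \code{model_decision}: per-stage records,
#'   \code{finalists}, and \code{decision} (a model name or
#'   \code{"indistinguishable"}).
#' @export
select_best <- function(results, alpha_level = 0.05) {
  if (!length(results)) stop("empty result list")
  for (r in results) stopifnot(inherits(r, "pmc_result"))
  ids <- vapply(results, function(r) r$data_id, character(1))
  if (length(unique(ids)) != 1L) {
    stop("pmc results were computed on different data")
  }
  find_pair <- function(null, test) {
    for (r in results) {
      if (r$null_model$model == null && r$test_model$model == test) return(r)
    }
    NULL
  }
  stages <- list()
  ## within BM
  best_bm <- NULL
  bm <- find_pair("BM1", "BM2")
  if (!is.null(bm)) {
    best_bm <- if (bm$p_value < alpha_level) "BM2" else "BM1"
    stages$bm <- list(pair = c("BM1", "BM2"), p = bm$p_value,
                      power = bm$power, chosen = best_bm)
  }
  ## within OU
  best_ou <- NULL
  ou12 <- find_pair("OU1", "OU2")
  if (!is.null(ou12)) {
    best_ou <- if (ou12$p_value < alpha_level) "OU2" else "OU1"
    stages$ou12 <- list(pair = c("OU1", "OU2"), p = ou12$p_value,
                        power = ou12$power, chosen = best_ou)
    if (best_ou == "OU2") {
      ou23 <- find_pair("OU2", "OU3")
      if (!is.null(ou23)) {
        best_ou <- if (ou23$p_value < alpha_level) "OU3" else "OU2"
        stages$ou23 <- list(pair = c("OU2", "OU3"), p = ou23$p_value,
                            power = ou23$power, chosen = best_ou)
      }
    }
  }
  finalists <- c(best_bm, best_ou)
  decision <- NA_character_
  if (length(finalists) == 2L) {
    cross <- find_pair(best_bm, best_ou)
    reversed <- FALSE
    if (is.null(cross)) {
      cross <- find_pair(best_ou, best_bm)
      reversed <- TRUE
    }
    if (!is.null(cross)) {
      null_hi <- nearest_rank_quantile(cross$null_dist, 0.95)
      test_lo <- nearest_rank_quantile(cross$test_dist, 0.05)
      d <- cross$delta_obs
      decision <- if (d > null_hi && d >= test_lo) {
        cross$test_model$model
      } else if (d <= null_hi && d < test_lo) {
        cross$null_model$model
      } else {
        "indistinguishable"
      }
      stages$cross <- list(pair = c(cross$null_model$model,
                                    cross$test_model$model),
                           delta_obs = d, null_q95 = null_hi,
                           test_q05 = test_lo, power = cross$power,
                           chosen = decision, reversed = reversed)
    }
  } else if (length(finalists) == 1L) {
    decision <- finalists
  }
  structure(list(stages = stages, finalists = finalists, decision = decision),
            class = "model_decision")
}

#' @export
print.model_decision <- function(x, ...) {
  cat("Staged model selection\n")
  for (nm in names(x$stages)) {
    s <- x$stages[[nm]]
    if (!is.null(s$p)) {
      cat(sprintf("  %s vs %s: p = %.4f, power = %.3f -> %s\n",
                  s$pair[1], s$pair[2], s$p, s$power, s$chosen))
    } else {
      cat(sprintf("  %s vs %s: delta = %.3f (null 95th %.3f, test 5th %.3f) -> %s\n",
                  s$pair[1], s$pair[2], s$delta_obs, s$null_q95, s$test_q05,
                  s$chosen))
    }
  }
  cat("  decision:", x$decision, "\n")
  invisible(x)
}

#' Robustness of rate estimates and power to lineage sample size
#'
#' For each subset size k, draws random subsets of the tips belonging to the
#' target regime, prunes the tree to those tips plus all other tips, repaints,
#' refits the two-rate Brownian model, and runs a (reduced-replicate)
#' parametric-bootstrap BM1-vs-BM2 comparison. This probes whether a rate
#' difference between lineages is an artefact of unequal population counts
#' and how detection power grows with sampling.
#'
#' @param tree An (unpainted or painted) ultrametric tree.
#' @param y Named trait vector for all tips.
#' @param tip_regimes Named regime map for all tips.
#' @param regime The regime whose tips are subsampled.
#' @param k_range Integer vector of subset sizes (each >= 2 and <= the number
#'   of tips in the regime).
#' @param n_draws Random subsets per k.
#' @param n_reps Bootstrap replicates for the power estimate per draw.
#' @param seed Integer seed.
#' @param groups Rate grouping passed to the BM2 fit (default as in
#'   \code{\link{fit_trait_model}}).
#' @param interior_rule Painting rule after pruning.
#' @return Data frame with one row per (k, draw): the fitted per-group rates,
#'   \code{p_value} and \code{power}.
#' @export
subsample_robustness <- function(tree, y, tip_regimes, regime, k_range,
                                 n_draws = 10L, n_reps = 100L, seed = 1L,
                                 groups = NULL,
                                 interior_rule = "parsimony") {
  stopifnot(inherits(tree, "phylo"))
  target <- names(tip_regimes)[tip_regimes == regime]
  target <- intersect(target, tree$tip.label)
  if (!length(target)) stop("no tips carry regime '", regime, "'")
  if (any(k_range < 2L)) stop("subset sizes below 2 are not allowed")
  if (any(k_range > length(target))) {
    stop("k exceeds the number of tips in regime '", regime, "'")
  }
  others <- setdiff(tree$tip.label, target)
  rows <- list()
  for (k in k_range) {
    for (d in seq_len(n_draws)) {
      sel <- with_seed(child_seed(seed, k * 1000L + d),
                       sample(target, k))
      keep <- c(others, sel)
      sub <- prune_tree(tree, keep)
      sub <- paint_regimes(sub, tip_regimes[keep],
                           interior_rule = interior_rule)
      sub <- rescale_tree_height(sub)
      ys <- y[keep]
      res <- tryCatch(
        pmc_compare(sub, ys, "BM1", list(model = "BM2", groups = groups),
                    n_reps = n_reps, seed = child_seed(seed, k * 1000L + d)),
        error = function(e) NULL)
      if (is.null(res)) next
      s2 <- res$fit_test$par$sigma2
      row <- data.frame(k = k, draw = d, p_value = res$p_value,
                        power = res$power)
      for (g in names(s2)) row[[paste0("sigma2.", g)]] <- s2[[g]]
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}
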