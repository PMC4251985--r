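## ---- internal profiled likelihoods ------------------------------------------

## BM with rates proportional to exp(logrho) per rate group; root state and
## overall scale profiled out by GLS. Cg: list of per-group shared-path
## matrices. Returns logL plus estimates.
bm_profile <- function(td, y, Cg, logrho) {
  rho <- c(1, exp(logrho))
  A <- Reduce(`+`, Map(`*`, Cg, rho))
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(R)) return(list(logLik = -Inf))
  n <- td$n
  one <- rep(1, n)
  Li1 <- backsolve(R, one, transpose = TRUE)
  Liy <- backsolve(R, y, transpose = TRUE)
  z0 <- sum(Li1 * Liy) / sum(Li1^2)
  q <- sum((Liy - z0 * Li1)^2)
  s2 <- q / n
  logLik <- -0.5 * n * log(2 * pi * s2) - sum(log(diag(R))) - 0.5 * n
  list(logLik = logLik, z0 = z0, scale = s2, rho = rho)
}

## OU at fixed alpha: optima profiled by GLS, gamma = sigma2/(2 alpha)
## profiled analytically. G: n x m group design aggregation of the regime
## weight matrix, root weight added to the root regime's group column.
ou_profile <- function(td, y, alpha, group_of_regime, use_cache = FALSE) {
  st <- if (use_cache) ou_structure_cached(td, alpha) else
    ou_structure(td, alpha)
  groups <- unique(group_of_regime)
  m <- length(groups)
  G <- matrix(0, td$n, m, dimnames = list(NULL, groups))
  for (k in seq_along(td$regimes)) {
    g <- group_of_regime[[td$regimes[k]]]
    G[, g] <- G[, g] + st$W[, k]
  }
  root_g <- group_of_regime[[td$root_regime]]
  G[, root_g] <- G[, root_g] + st$root_weight
  R <- tryCatch(chol(st$A), error = function(e) NULL)
  if (is.null(R)) return(list(logLik = -Inf))
  LiG <- backsolve(R, G, transpose = TRUE)
  Liy <- backsolve(R, y, transpose = TRUE)
  XtX <- crossprod(LiG)
  theta <- tryCatch(solve(XtX, crossprod(LiG, Liy)),
                    error = function(e) NULL)
  if (is.null(theta)) return(list(logLik = -Inf))
  r <- Liy - LiG %*% theta
  n <- td$n
  gam <- sum(r^2) / n
  if (gam <= 0) return(list(logLik = -Inf))
  logLik <- -0.5 * n * log(2 * pi * gam) - sum(log(diag(R))) - 0.5 * n
  list(logLik = logLik, theta = stats::setNames(as.vector(theta), groups),
       gamma = gam, alpha = alpha, sigma2 = 2 * alpha * gam)
}

## default mapping regime -> parameter group for 1/2/3-parameter structures
default_groups <- function(reg_levels, k) {
  if (k == 1L) {
    return(stats::setNames(rep("all", length(reg_levels)), reg_levels))
  }
  if (k == length(reg_levels)) {
    return(stats::setNames(reg_levels, reg_levels))
  }
  if (k == 2L && setequal(reg_levels, c("JS", "PO_anad", "PO_fresh"))) {
    ## canonical lineage grouping: freshwater populations stay in their lineage
    return(c(JS = "JS", PO_anad = "PO", PO_fresh = "PO"))
  }
  stop(sprintf(
    "cannot derive a default %d-group structure from regimes {%s}; supply 'groups'",
    k, paste(reg_levels, collapse = ", ")))
}

check_groups <- function(td, groups) {
  if (!all(td$regimes %in% names(groups))) {
    stop("'groups' must map every regime: ", paste(td$regimes, collapse = ", "))
  }
  groups <- groups[td$regimes]
  ## every group must own at least one branch with positive length
  for (g in unique(groups)) {
    regs <- names(groups)[groups == g]
    tot <- sum(vapply(regs, function(r) sum(td$Ck[[r]][cbind(seq_len(td$n), seq_len(td$n))]),
                      numeric(1)))
    if (tot <= 0) {
      stop("degenerate parameter group '", g, "': no branch carries its regimes")
    }
  }
  groups
}

## ---- public fitting ---------------------------------------------------------

#' Fit a trait-evolution model on a regime-painted tree
#'
#' Maximum-likelihood fit of Brownian-motion (single- or multi-rate) or
#' Ornstein-Uhlenbeck (1/2/3-optimum) models of continuous trait evolution.
#' BM profiles the root state by generalised least squares and the overall
#' rate analytically, leaving at most a one-dimensional search over the rate
#' ratio. OU shares one selection strength \code{alpha} and one diffusion rate
#' \code{sigma2} across regimes and fits regime-group optima by GLS at each
#' \code{alpha}; \code{alpha} is searched on a log grid and the best grid
#' points are polished by bounded one-dimensional optimisation (five starts).
#' The OU root state equals the optimum of the root's regime.
#'
#' @param tree A tree painted by \code{\link{paint_regimes}}. For comparable
#'   rates across trees, rescale to unit height first
#'   (\code{\link{rescale_tree_height}}).
#' @param y Named numeric trait vector covering the tips.
#' @param model One of \code{"BM1"}, \code{"BM2"}, \code{"OU1"}, \code{"OU2"},
#'   \code{"OU3"}.
#' @param groups Named character vector mapping each regime to a parameter
#'   group (rate group for BM2; optimum group for OU2/OU3). Defaults: one
#'   group for BM1/OU1; one group per regime when the regime count matches;
#'   for two-group models on the canonical three regimes
#'   \{JS, PO_anad, PO_fresh\}, the freshwater regime is grouped with its
#'   lineage (\code{PO}).
#' @param alpha_grid Log-spaced grid of selection strengths (inverse
#'   tree-height units) scanned for OU models.
#' @return An object of class \code{trait_fit}; see
#'   \code{\link{print.trait_fit}}, \code{\link{coef.trait_fit}},
#'   \code{\link{simulate.trait_fit}}, \code{\link{bootstrap_ci}}.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1.5,D:1.5):0.5);")
#' tr <- paint_regimes(tr, c(A = "x", B = "x", C = "y", D = "y"))
#' y <- c(A = 1.1, B = 0.8, C = 3.2, D = 2.9)
#' fit_trait_model(tr, y, "OU2")
#' @export
fit_trait_model <- function(tree, y,
                            model = c("BM1", "BM2", "OU1", "OU2", "OU3"),
                            groups = NULL,
                            alpha_grid = NULL) {
  model <- match.arg(model)
  td <- if (inherits(tree, "tree_data")) tree else tree_data(tree)
  y <- align_traits(td, y)
  k <- c(BM1 = 1L, BM2 = 2L, OU1 = 1L, OU2 = 2L, OU3 = 3L)[[model]]
  if (is.null(groups)) groups <- default_groups(td$regimes, k)
  groups <- check_groups(td, groups)
  n_groups <- length(unique(groups))
  if (n_groups > k) {
    stop(sprintf("model %s allows at most %d parameter group(s), got %d",
                 model, k, n_groups))
  }
  fit <- if (startsWith(model, "BM")) {
    fit_bm_internal(td, y, groups)
  } else {
    fit_ou_internal(td, y, groups, alpha_grid)
  }
  df <- if (startsWith(model, "BM")) 1L + n_groups else 2L + n_groups
  structure(
    c(fit,
      list(model = model, groups = groups, y = y, td = td,
           n = td$n, data_id = data_id(y), df = df)),
    class = "trait_fit")
}

data_id <- function(y) {
  paste(names(y), format(unname(y), digits = 15), collapse = ";")
}

fit_bm_internal <- function(td, y, groups) {
  glabels <- unique(groups)
  Cg <- lapply(glabels, function(g) {
    regs <- names(groups)[groups == g]
    Reduce(`+`, td$Ck[regs])
  })
  names(Cg) <- glabels
  if (length(glabels) == 1L) {
    prof <- bm_profile(td, y, Cg, numeric(0))
    if (!is.finite(prof$logLik)) stop("Brownian-motion covariance is singular")
    rates <- stats::setNames(prof$scale, glabels)
    conv <- list(converged = TRUE, boundary = FALSE)
  } else {
    obj <- function(lr) bm_profile(td, y, Cg, lr)$logLik
    opt <- stats::optimize(obj, interval = c(-15, 15), maximum = TRUE,
                           tol = 1e-10)
    ## guard against a missed interior optimum at equal rates
    cand <- c(opt$maximum, 0)
    lls <- vapply(cand, obj, numeric(1))
    lr <- cand[which.max(lls)]
    prof <- bm_profile(td, y, Cg, lr)
    rates <- stats::setNames(prof$scale * prof$rho, glabels)
    conv <- list(converged = is.finite(prof$logLik),
                 boundary = abs(lr) >= 15 - 1e-6)
  }
  list(family = "BM",
       par = list(z0 = prof$z0, sigma2 = rates),
       logLik = prof$logLik, convergence = conv)
}

fit_ou_internal <- function(td, y, groups, alpha_grid = NULL) {
  if (is.null(alpha_grid)) {
    alpha_grid <- exp(seq(log(1e-2), log(50), length.out = 14)) / td$height
  }
  lls <- vapply(alpha_grid,
                function(a) ou_profile(td, y, a, groups,
                                       use_cache = TRUE)$logLik,
                numeric(1))
  ord <- order(lls, decreasing = TRUE)
  ## polish from the best grid points (jittered multi-start in log alpha);
  ## a 1e-4 tolerance on log(alpha) resolves the profile log-likelihood far
  ## below 1e-8 near its quadratic optimum
  starts <- alpha_grid[ord[seq_len(min(5L, length(alpha_grid)))]]
  step <- diff(log(alpha_grid))[1]
  best <- list(logLik = -Inf)
  obj <- function(la) ou_profile(td, y, exp(la), groups)$logLik
  for (a0 in starts) {
    opt <- tryCatch(
      stats::optimize(obj, interval = log(a0) + c(-step, step) * 1.1,
                      maximum = TRUE, tol = 1e-4),
      error = function(e) NULL)
    if (is.null(opt)) next
    prof <- ou_profile(td, y, exp(opt$maximum), groups)
    if (prof$logLik > best$logLik) best <- prof
  }
  if (!is.finite(best$logLik)) stop("OU fit failed at every alpha start")
  rng <- range(alpha_grid)
  boundary <- best$alpha <= rng[1] * exp(step * 0.5) ||
              best$alpha >= rng[2] / exp(step * 0.5)
  ## flat-likelihood diagnostic: spread of profile logL across the grid
  flat <- max(lls[is.finite(lls)]) - min(lls[is.finite(lls)]) < 1e-6
  list(family = "OU",
       par = list(alpha = best$alpha, sigma2 = best$sigma2,
                  theta = best$theta,
                  z0 = best$theta[[groups[[td$root_regime]]]]),
       logLik = best$logLik,
       convergence = list(converged = TRUE, boundary = boundary, flat = flat))
}

#' @rdname fit_trait_model
#' @param n_rates For \code{fit_bm}: 1 (single rate) or 2 (separate rates).
#' @export
fit_bm <- function(tree, y, n_rates = 1L, groups = NULL) {
  fit_trait_model(tree, y, if (n_rates == 1L) "BM1" else "BM2", groups)
}

#' @rdname fit_trait_model
#' @param optima_structure For \code{fit_ou}: \code{"OU1"}, \code{"OU2"} or
#'   \code{"OU3"}.
#' @export
fit_ou <- function(tree, y, optima_structure = c("OU1", "OU2", "OU3"),
                   groups = NULL) {
  fit_trait_model(tree, y, match.arg(optima_structure), groups)
}

## ---- methods ----------------------------------------------------------------

#' @export
print.trait_fit <- function(x, digits = 4, ...) {
  cat(sprintf("%s trait-evolution model fit (%d tips)\n", x$model, x$n))
  cat(sprintf("  log-likelihood: %.*f  (df = %d)\n", digits, x$logLik, x$df))
  if (x$family == "BM") {
    cat(sprintf("  root state z0 = %.*g\n", digits, x$par$z0))
    for (g in names(x$par$sigma2)) {
      cat(sprintf("  sigma^2[%s] = %.*g\n", g, digits, x$par$sigma2[[g]]))
    }
  } else {
    cat(sprintf("  alpha = %.*g, sigma^2 = %.*g\n",
                digits, x$par$alpha, digits, x$par$sigma2))
    for (g in names(x$par$theta)) {
      cat(sprintf("  theta[%s] = %.*g\n", g, digits, x$par$theta[[g]]))
    }
  }
  if (isTRUE(x$convergence$boundary)) cat("  note: estimate at search boundary\n")
  if (!is.null(x$ci)) {
    cat("  bootstrap 95% CIs:\n")
    print(round(x$ci, digits))
  }
  invisible(x)
}

#' @export
summary.trait_fit <- function(object, ...) {
  out <- list(model = object$model, n = object$n,
              coef = coef(object), logLik = object$logLik, df = object$df,
              convergence = object$convergence, ci = object$ci,
              residuals = stats::residuals(object))
  class(out) <- "summary.trait_fit"
  out
}

#' @export
print.summary.trait_fit <- function(x, ...) {
  cat(sprintf("%s model, n = %d tips, logLik = %.4f (df = %d)\n",
              x$model, x$n, x$logLik, x$df))
  cat("Coefficients:\n")
  print(x$coef)
  if (!is.null(x$ci)) {
    cat("Bootstrap 95% CIs:\n")
    print(x$ci)
  }
  cat("Residual summary (observed - expected tip values):\n")
  print(summary(unname(x$residuals)))
  invisible(x)
}

#' @export
coef.trait_fit <- function(object, ...) {
  p <- object$par
  if (object$family == "BM") {
    c(z0 = unname(p$z0),
      stats::setNames(as.numeric(p$sigma2), paste0("sigma2.", names(p$sigma2))))
  } else {
    c(alpha = unname(p$alpha), sigma2 = unname(p$sigma2),
      stats::setNames(as.numeric(p$theta), paste0("theta.", names(p$theta))))
  }
}

#' @export
logLik.trait_fit <- function(object, ...) {
  structure(object$logLik, df = object$df, nobs = object$n, class = "logLik")
}

#' Expected tip values under a fitted trait model
#'
#' @param object A \code{trait_fit}.
#' @param ... Unused.
#' @return Named vector of model-expected tip means (BM: the root state; OU:
#'   the optima-weighted Hansen means).
#' @export
predict.trait_fit <- function(object, ...) {
  td <- object$td
  if (object$family == "BM") {
    return(stats::setNames(rep(object$par$z0, td$n), td$tips))
  }
  st <- ou_structure(td, object$par$alpha)
  theta_reg <- expand_group_par(object$par$theta, object$groups)
  mu <- as.vector(st$W %*% theta_reg[td$regimes]) +
    object$par$z0 * st$root_weight
  stats::setNames(mu, td$tips)
}

#' @export
residuals.trait_fit <- function(object, ...) {
  object$y - predict(object)
}

expand_group_par <- function(par_by_group, groups) {
  stats::setNames(as.numeric(par_by_group[groups]), names(groups))
}

#' Plot a fitted trait model
#'
#' Draws the painted tree with tip symbols scaled by the trait value and, for
#' OU fits, dashed reference lines at the fitted optima.
#'
#' @param x A \code{trait_fit}.
#' @param ... Passed to \code{\link[ape]{plot.phylo}}.
#' @export
plot.trait_fit <- function(x, ...) {
  td <- x$td
  graphics::plot(seq_len(td$n), x$y, xaxt = "n",
                 xlab = "tip", ylab = "trait value",
                 main = sprintf("%s fit", x$model), ...)
  graphics::axis(1, at = seq_len(td$n), labels = td$tips, las = 2,
                 cex.axis = 0.7)
  mu <- predict(x)
  graphics::points(seq_len(td$n), mu, pch = 4, col = "red")
  if (x$family == "OU") {
    graphics::abline(h = x$par$theta, lty = 2, col = "grey40")
  }
  graphics::legend("topright", pch = c(1, 4), col = c("black", "red"),
                   legend = c("observed", "expected"), bty = "n")
  invisible(x)
}

#' Parametric-bootstrap confidence intervals for a trait-model fit
#'
#' Simulates \code{n_reps} datasets under the fitted model, refits the same
#' model family to each, and reports percentile 2.5/97.5 intervals for every
#' parameter. Refit failures are dropped and counted; if more than 20% fail
#' the intervals are flagged.
#'
#' @param fit A \code{trait_fit}.
#' @param n_reps Number of bootstrap replicates.
#' @param seed Integer seed.
#' @return The fit with components \code{ci} (data frame: estimate, lower,
#'   upper) and \code{ci_meta} (n_reps, failures, flagged).
#' @export
bootstrap_ci <- function(fit, n_reps = 200L, seed = 1L) {
  stopifnot(inherits(fit, "trait_fit"))
  if (n_reps < 2L) {
    warning("n_reps < 2 gives a degenerate interval; flagged")
  }
  sims <- simulate(fit, nsim = n_reps, seed = seed)
  if (n_reps == 1L) sims <- matrix(sims, ncol = 1L)
  boots <- matrix(NA_real_, n_reps, length(coef(fit)),
                  dimnames = list(NULL, names(coef(fit))))
  for (r in seq_len(n_reps)) {
    yr <- stats::setNames(sims[, r], fit$td$tips)
    ref <- tryCatch(fit_trait_model(fit$td, yr, fit$model, fit$groups),
                    error = function(e) NULL)
    if (!is.null(ref)) boots[r, ] <- coef(ref)
  }
  ok <- stats::complete.cases(boots)
  n_fail <- sum(!ok)
  ci <- t(apply(boots[ok, , drop = FALSE], 2, stats::quantile,
                probs = c(0.025, 0.975), names = FALSE))
  out <- data.frame(estimate = coef(fit), lower = ci[, 1], upper = ci[, 2])
  fit$ci <- out
  fit$ci_meta <- list(n_reps = n_reps, n_fail = n_fail,
                      flagged = n_fail > 0.2 * n_reps || n_reps < 2L)
  if (fit$ci_meta$flagged && n_fail > 0.2 * n_reps) {
    warning(sprintf("bootstrap CI flagged: %d of %d refits failed",
                    n_fail, n_reps))
  }
  fit
}

#' Serialize a trait-model fit to JSON
#'
#' Writes the model family, parameter estimates, log-likelihood and (when
#' present) bootstrap confidence intervals.
#'
#' @param fit A \code{trait_fit}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_trait_fit <- function(fit, path) {
  stopifnot(inherits(fit, "trait_fit"))
  obj <- list(model = fit$model, family = fit$family,
              coef = as.list(coef(fit)), logLik = fit$logLik, df = fit$df,
              n = fit$n, groups = as.list(fit$groups),
              convergence = fit$convergence)
  if (!is.null(fit$ci)) {
    obj$ci <- cbind(parameter = rownames(fit$ci), fit$ci)
    obj$ci_meta <- fit$ci_meta
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @export
confint.trait_fit <- function(object, parm, level = 0.95, ...) {
  if (is.null(object$ci)) {
    stop("no bootstrap intervals stored; run bootstrap_ci() first")
  }
  ci <- object$ci[, c("lower", "upper")]
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  as.matrix(ci)
}
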