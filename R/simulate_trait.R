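#' Simulate trait evolution on a regime-painted tree
#'
#' Simulates tip trait values by preorder recursion. Under Brownian motion a
#' child node is the parent plus \eqn{N(0, \sigma^2_{regime} \ell)}; under OU
#' the child is
#' \eqn{x_p e^{-\alpha\ell} + \theta_{regime}(1 - e^{-\alpha\ell}) +
#' N\!\left(0, \sigma^2 (1 - e^{-2\alpha\ell})/(2\alpha)\right)} where
#' \eqn{\ell} is the branch length.
#'
#' @param tree A regime-painted tree (or a \code{trait_fit}'s stored tree
#'   data).
#' @param params Either a \code{\link{fit_trait_model}} fit (its estimates are
#'   used) or a list: for BM \code{list(family = "BM", z0, sigma2)} with
#'   \code{sigma2} named per regime; for OU
#'   \code{list(family = "OU", alpha, sigma2, theta)} with \code{theta} named
#'   per regime and optional \code{z0} (default: the root regime's optimum).
#' @param seed Integer seed; the same seed always yields the same traits.
#' @param nsim Number of independent replicate simulations.
#' @return If \code{nsim = 1}, a named trait vector; otherwise an
#'   \code{n x nsim} matrix with tip labels as row names.
#' @export
simulate_trait <- function(tree, params, seed = 1L, nsim = 1L) {
  td <- if (inherits(tree, "tree_data")) tree else tree_data(tree)
  p <- normalize_sim_params(td, params)
  nn <- td$n + td$n_node
  root <- td$n + 1L
  with_seed(seed, {
    x <- matrix(NA_real_, nn, nsim)
    x[root, ] <- p$z0
    for (e in seq_len(nrow(td$edge))) {
      par_node <- td$edge[e, 1]; child <- td$edge[e, 2]
      len <- td$edge.length[e]
      reg <- td$edge_regime[e]
      if (p$family == "BM") {
        sd_e <- sqrt(p$sigma2[[reg]] * len)
        x[child, ] <- x[par_node, ] +
          if (sd_e > 0) stats::rnorm(nsim, 0, sd_e) else 0
      } else {
        w <- exp(-p$alpha * len)
        v <- p$sigma2 * (-expm1(-2 * p$alpha * len)) / (2 * p$alpha)
        x[child, ] <- x[par_node, ] * w + p$theta[[reg]] * (1 - w) +
          stats::rnorm(nsim, 0, sqrt(v))
      }
    }
    out <- x[seq_len(td$n), , drop = FALSE]
    rownames(out) <- td$tips
    if (nsim == 1L) out[, 1] else out
  })
}

normalize_sim_params <- function(td, params) {
  if (inherits(params, "trait_fit")) {
    g <- params$groups
    if (params$family == "BM") {
      return(list(family = "BM", z0 = params$par$z0,
                  sigma2 = expand_group_par(params$par$sigma2, g)))
    }
    theta <- expand_group_par(params$par$theta, g)
    return(list(family = "OU", alpha = params$par$alpha,
                sigma2 = params$par$sigma2, theta = theta,
                z0 = params$par$z0))
  }
  family <- params$family
  if (identical(family, "BM")) {
    s2 <- expand_rates(params$sigma2, td$regimes)
    if (any(s2 < 0)) stop("sigma2 must be >= 0")
    return(list(family = "BM", z0 = params$z0, sigma2 = s2))
  }
  if (identical(family, "OU")) {
    if (params$alpha <= 0 || params$sigma2 <= 0) {
      stop("OU simulation needs alpha > 0 and sigma2 > 0")
    }
    theta <- params$theta
    if (!all(td$regimes %in% names(theta))) {
      stop("theta must be named for every regime")
    }
    z0 <- params$z0 %||% theta[[td$root_regime]]
    return(list(family = "OU", alpha = params$alpha, sigma2 = params$sigma2,
                theta = theta, z0 = z0))
  }
  stop("params$family must be 'BM' or 'OU'")
}

#' @rdname simulate_trait
#' @param object A \code{trait_fit}.
#' @param ... Unused.
#' @export
simulate.trait_fit <- function(object, nsim = 1L, seed = 1L, ...) {
  simulate_trait(object$td, object, seed = seed, nsim = nsim)
}
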