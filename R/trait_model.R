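## ---- internal tree pre-processing for trait models -------------------------

## Collects everything the BM/OU likelihoods need from a regime-painted
## ultrametric tree: node depths, MRCA heights, per-regime shared root-to-MRCA
## branch lengths, and per-tip path segments (for the OU mean construction).
tree_data <- function(tree) {
  reg <- regimes(tree)                      # errors if unpainted
  n <- length(tree$tip.label)
  if (n < 2L) stop("need at least 2 tips")
  depth <- ape::node.depth.edgelength(tree) # time from root, all nodes
  TT <- max(depth[seq_len(n)])
  if (max(depth[seq_len(n)]) - min(depth[seq_len(n)]) > 1e-6 * max(TT, 1)) {
    stop("tree is not ultrametric within tolerance")
  }
  reg_levels <- sort(unique(c(reg, attr(tree, "root_regime"))))
  K <- length(reg_levels)
  reg_idx <- match(reg, reg_levels)
  ## per-node per-regime root-to-node branch length (preorder accumulation)
  nn <- n + tree$Nnode
  rl <- matrix(0, nn, K, dimnames = list(NULL, reg_levels))
  reg_of_edge <- stats::setNames(reg_idx,
                                 paste(tree$edge[, 1], tree$edge[, 2]))
  pre <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(pre$edge))) {
    p <- pre$edge[e, 1]; ch <- pre$edge[e, 2]
    len <- pre$edge.length[e]
    k <- reg_of_edge[[paste(p, ch)]]
    rl[ch, ] <- rl[p, ]
    rl[ch, k] <- rl[ch, k] + len
  }
  mrca <- ape::mrca(tree)                   # n x n internal node numbers
  diag(mrca) <- seq_len(n)
  S <- matrix(depth[mrca], n, n)            # shared height from root
  D <- outer(depth[seq_len(n)], depth[seq_len(n)], "+") - 2 * S  # patristic
  Ck <- lapply(seq_len(K), function(k) matrix(rl[mrca, k], n, n))
  names(Ck) <- reg_levels
  ## path segments: one row per (tip, branch on its root path)
  segs <- path_segments(tree, depth, reg_idx)
  ## preorder edge list for simulation
  pre_key <- paste(pre$edge[, 1], pre$edge[, 2])
  structure(
    list(n = n, tips = tree$tip.label, height = TT, depth = depth,
         regimes = reg_levels, K = K, S = S, D = D, Ck = Ck,
         seg_tip = segs$tip, seg_t1 = segs$t1, seg_t2 = segs$t2,
         seg_reg = segs$reg, root_regime = attr(tree, "root_regime"),
         edge = pre$edge, edge.length = pre$edge.length,
         edge_regime = reg_levels[reg_of_edge[pre_key]],
         n_node = tree$Nnode,
         cache = new.env(parent = emptyenv())),
    class = "tree_data")
}

path_segments <- function(tree, depth, reg_idx) {
  n <- length(tree$tip.label)
  tip <- integer(0); t1 <- numeric(0); t2 <- numeric(0); rg <- integer(0)
  for (e in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[e, 2]
    tips_below <- tip_descendants(tree, ch)
    m <- length(tips_below)
    tip <- c(tip, tips_below)
    t1 <- c(t1, rep(depth[tree$edge[e, 1]], m))
    t2 <- c(t2, rep(depth[ch], m))
    rg <- c(rg, rep(reg_idx[e], m))
  }
  list(tip = tip, t1 = t1, t2 = t2, reg = rg)
}

## multivariate normal log density via Cholesky; informative failure
loglik_mvn <- function(y, mu, V, context = "covariance") {
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) {
    stop(sprintf("%s matrix is not positive definite (min diagonal %.3g, min branch contribution %.3g)",
                 context, min(diag(V)), min(V)))
  }
  r <- y - mu
  z <- backsolve(R, r, transpose = TRUE)
  -0.5 * length(y) * log(2 * pi) - sum(log(diag(R))) - 0.5 * sum(z^2)
}

## align a trait vector with the tree's tips
align_traits <- function(td, y) {
  if (is.null(names(y))) stop("trait vector must be named by tip label")
  missing <- setdiff(td$tips, names(y))
  if (length(missing)) stop("traits missing for tip(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(names(y), td$tips)
  if (length(extra)) stop("traits for unknown tip(s): ", paste(extra, collapse = ", "))
  y <- y[td$tips]
  if (any(!is.finite(y))) stop("non-finite trait values")
  y
}

## ---- Brownian motion --------------------------------------------------------

#' Brownian-motion log-likelihood on a regime-painted tree
#'
#' Log density of tip traits under multivariate-normal Brownian motion with
#' root state \code{z0} and per-regime rates: the covariance between two tips
#' is the sum over branches on the root-to-MRCA path of
#' \eqn{\sigma^2_{regime} \times length}.
#'
#' @param tree A tree painted by \code{\link{paint_regimes}}.
#' @param y Named numeric trait vector covering the tree's tips.
#' @param z0 Root (ancestral) state.
#' @param rates Named vector of per-regime rates \eqn{\sigma^2 > 0}; a single
#'   unnamed value is recycled to all regimes.
#' @return Log-likelihood (scalar).
#' @export
bm_loglik <- function(tree, y, z0, rates) {
  td <- tree_data(tree)
  y <- align_traits(td, y)
  rates <- expand_rates(rates, td$regimes)
  if (any(rates <= 0)) stop("rates must be positive")
  V <- Reduce(`+`, Map(function(k) rates[k] * td$Ck[[k]], td$regimes))
  loglik_mvn(y, rep(z0, td$n), V, "Brownian-motion covariance")
}

expand_rates <- function(rates, regs) {
  if (length(rates) == 1L && is.null(names(rates))) {
    return(stats::setNames(rep(rates, length(regs)), regs))
  }
  if (!all(regs %in% names(rates))) {
    stop("rates must be named for every regime: ", paste(regs, collapse = ", "))
  }
  rates[regs]
}

## ---- Ornstein-Uhlenbeck -----------------------------------------------------

## OU mean/covariance building blocks at a given alpha (Hansen construction,
## fixed root state, ultrametric tree). Grid alphas recur across bootstrap
## refits, so structures may be memoised in the tree's cache environment.
ou_structure_cached <- function(td, alpha) {
  key <- sprintf("a%.17g", alpha)
  if (!is.null(td$cache) && !is.null(td$cache[[key]])) {
    return(td$cache[[key]])
  }
  st <- ou_structure(td, alpha)
  if (!is.null(td$cache)) td$cache[[key]] <- st
  st
}

ou_structure <- function(td, alpha) {
  A <- exp(-alpha * td$D) * (-expm1(-2 * alpha * td$S))
  w <- exp(-alpha * (td$height - td$seg_t2)) -
       exp(-alpha * (td$height - td$seg_t1))
  idx <- (td$seg_reg - 1L) * td$n + td$seg_tip
  W <- matrix(0, td$n, td$K, dimnames = list(NULL, td$regimes))
  agg <- rowsum(w, group = idx)
  W[as.integer(rownames(agg))] <- agg
  list(A = A, W = W, root_weight = exp(-alpha * td$height))
}

#' Ornstein-Uhlenbeck log-likelihood on a regime-painted tree
#'
#' Multivariate-normal log density under a multi-optimum OU process with a
#' single selection strength \code{alpha} and diffusion rate \code{sigma2}
#' shared across regimes (the Hansen convention), regime-specific optima
#' \code{theta}, and a fixed root state. For an ultrametric tree the
#' covariance between tips i and j is
#' \eqn{\sigma^2/(2\alpha)\, e^{-\alpha d_{ij}} (1 - e^{-2\alpha s_{ij}})}
#' with \eqn{d_{ij}} the patristic distance and \eqn{s_{ij}} the shared
#' height; each tip's expectation weights the optima along its root-to-tip
#' path by \eqn{e^{-\alpha(T-t_2)} - e^{-\alpha(T-t_1)}}, plus
#' \eqn{z_0 e^{-\alpha T}} for the root.
#'
#' @param tree A tree painted by \code{\link{paint_regimes}}.
#' @param y Named numeric trait vector.
#' @param alpha Selection strength (> 0), in inverse tree-height units.
#' @param sigma2 Diffusion rate (> 0).
#' @param optima Named vector of per-regime optima \eqn{\theta}.
#' @param root Either \code{"root_regime"} (root state equals the optimum of
#'   the root's regime, the default) or a numeric root state.
#' @return Log-likelihood (scalar).
#' @export
ou_loglik <- function(tree, y, alpha, sigma2, optima, root = "root_regime") {
  if (alpha <= 0) stop("'alpha' must be > 0")
  if (sigma2 <= 0) stop("'sigma2' must be > 0")
  td <- tree_data(tree)
  y <- align_traits(td, y)
  if (!all(td$regimes %in% names(optima))) {
    stop("optima must be named for every regime: ",
         paste(td$regimes, collapse = ", "))
  }
  st <- ou_structure(td, alpha)
  if (min(diag(st$A)) < 1e-300) {
    warning("alpha so large that OU covariance underflows; flooring")
    diag(st$A) <- pmax(diag(st$A), 1e-300)
  }
  z0 <- if (identical(root, "root_regime")) optima[[td$root_regime]] else root
  mu <- as.vector(st$W %*% optima[td$regimes]) + z0 * st$root_weight
  V <- (sigma2 / (2 * alpha)) * st$A
  loglik_mvn(y, mu, V, "Ornstein-Uhlenbeck covariance")
}
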