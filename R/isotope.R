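#' Lipid normalization of delta-13C
#'
#' Applies the three-parameter mass-balance lipid-normalization model for fish
#' muscle: lipid content is predicted from the C:N mass ratio by the logistic
#' \deqn{L = 93 / (1 + (0.246\,C{:}N - 0.775)^{-1})}
#' and the corrected value is
#' \deqn{\delta^{13}C' = \delta^{13}C + D\,(I + 3.90 / (1 + 287/L))}
#' with protein-lipid discrimination \code{D} = 7.018 and constant
#' \code{I} = 0.048. At the lipid-free reference C:N (about 3.15, where
#' L reaches 0) the correction bottoms out at \code{D * I} (about 0.34 per
#' mil) and it increases monotonically with C:N.
#'
#' @param d13c Numeric vector of delta-13C values (per mil).
#' @param cn Numeric vector of C:N mass ratios (> 0); \code{NA} passes the
#'   sample through uncorrected.
#' @param D,I Model constants.
#' @return Corrected delta-13C vector.
#' @export
lipid_normalize <- function(d13c, cn, D = 7.018, I = 0.048) {
  if (length(cn) == 1L) cn <- rep(cn, length(d13c))
  if (any(!is.na(cn) & cn <= 0)) stop("C:N must be > 0")
  L <- 93 / (1 + (0.246 * cn - 0.775)^-1)
  L[!is.na(L) & L < 0] <- 0          # below the lipid-free reference ratio
  corr <- D * (I + 3.90 / (1 + 287 / L))
  corr[!is.na(L) & L == 0] <- D * I
  out <- d13c + corr
  out[is.na(cn)] <- d13c[is.na(cn)]
  out
}

#' Lipid-normalize a sample table
#'
#' Data-frame front end for \code{\link{lipid_normalize}}: corrects
#' \code{d13C} in place using column \code{C_N}, sets the
#' \code{lipid_normalized} flag, and is idempotent (already-flagged rows are
#' left untouched). Rows without a C:N value pass through with the flag
#' \code{FALSE}.
#'
#' @param samples Data frame with columns \code{d13C}, optionally \code{C_N}
#'   and \code{lipid_normalized}.
#' @return The corrected data frame.
#' @export
lipid_normalize_samples <- function(samples) {
  if (is.null(samples$lipid_normalized)) samples$lipid_normalized <- FALSE
  if (is.null(samples$C_N)) samples$C_N <- NA_real_
  todo <- !samples$lipid_normalized & !is.na(samples$C_N)
  samples$d13C[todo] <- lipid_normalize(samples$d13C[todo], samples$C_N[todo])
  samples$lipid_normalized[todo] <- TRUE
  samples
}

#' Two-source trophic position
#'
#' Post's two-baseline estimator. The benthic reliance
#' \eqn{\alpha = (\delta^{13}C_c - \delta^{13}C_{b2}) /
#' (\delta^{13}C_{b1} - \delta^{13}C_{b2})} is clamped to [0, 1] (with a
#' warning for consumers outside the baseline interval), and
#' \deqn{T_{POS} = \lambda + \left(\delta^{15}N_c -
#' [\alpha\,\delta^{15}N_{b1} + (1-\alpha)\,\delta^{15}N_{b2}]\right)/\Delta_n.}
#'
#' @param d13c,d15n Consumer values (vectors allowed).
#' @param base1,base2 Baselines: lists or named vectors with elements
#'   \code{d13C} and \code{d15N} (means of e.g. molluscs and bivalves
#'   characterising the two food webs).
#' @param lambda Trophic level of the baselines (2 for primary consumers).
#' @param delta_n Per-level delta-15N enrichment (default 3.4 per mil).
#' @return Numeric vector of trophic positions.
#' @examples
#' b1 <- c(d13C = -15, d15N = 8); b2 <- c(d13C = -25, d15N = 4)
#' trophic_position(-15, 8, b1, b2)        # consumer == baseline 1 -> 2
#' trophic_position(-20, 6 + 3.4, b1, b2)  # one level up the mix -> 3
#' @export
trophic_position <- function(d13c, d15n, base1, base2, lambda = 2,
                             delta_n = 3.4) {
  b1c <- base1[["d13C"]]; b1n <- base1[["d15N"]]
  b2c <- base2[["d13C"]]; b2n <- base2[["d15N"]]
  if (b1c == b2c) stop("baseline d13C means are equal; alpha is undefined")
  a <- (d13c - b2c) / (b1c - b2c)
  if (any(a < 0 | a > 1)) {
    warning("consumer d13C outside the baseline interval; alpha clamped to [0, 1]")
    a <- pmin(pmax(a, 0), 1)
  }
  lambda + (d15n - (a * b1n + (1 - a) * b2n)) / delta_n
}

#' Standard ellipse area of an isotopic niche
#'
#' Computes the standard ellipse area of a group's (d13C, d15N) scatter:
#' \eqn{SEA = \pi \sqrt{\det \hat\Sigma}} from the sample covariance, and the
#' small-sample corrected \eqn{SEA_C = SEA (n-1)/(n-2)}.
#'
#' @param d13c,d15n Numeric vectors (same length, n >= 3), or a two-column
#'   matrix/data frame in \code{d13c} with \code{d15n} missing.
#' @return Object of class \code{niche_ellipse}: \code{n}, \code{mean},
#'   \code{cov}, \code{SEA}, \code{SEA_C}.
#' @export
sea <- function(d13c, d15n = NULL) {
  x <- if (is.null(d15n)) as.matrix(d13c) else cbind(d13c, d15n)
  if (ncol(x) != 2L) stop("need two isotope axes")
  if (nrow(x) < 3L) stop("need at least 3 samples")
  S <- stats::cov(x)
  dt <- det(S)
  if (dt <= 0) stop("singular sample covariance; ellipse undefined")
  area <- pi * sqrt(dt)
  n <- nrow(x)
  structure(list(n = n, mean = colMeans(x), cov = S,
                 SEA = area, SEA_C = area * (n - 1) / (n - 2)),
            class = "niche_ellipse")
}

#' @export
print.niche_ellipse <- function(x, ...) {
  cat(sprintf("Isotopic niche ellipse (n = %d): SEA = %.4f, SEA_C = %.4f\n",
              x$n, x$SEA, x$SEA_C))
  if (!is.null(x$SEA_B)) {
    cat(sprintf("  SEA_B posterior mean %.4f (sd %.4f, %d draws)\n",
                mean(x$SEA_B), stats::sd(x$SEA_B), length(x$SEA_B)))
  }
  invisible(x)
}

#' Bayesian standard ellipse area
#'
#' Posterior draws of the standard ellipse area under a conjugate
#' normal-inverse-Wishart model with a vague prior: with the mean given a flat
#' prior, the covariance posterior is inverse-Wishart with degrees of freedom
#' \code{nu0 + n - 1} and scale \code{S0 + (n-1) * cov(x)}; prior
#' hyperparameters default to \code{nu0 = 3} and \code{S0 = 0.01 * I}. Each
#' draw's SEA is \eqn{\pi\sqrt{\det\Sigma}}. The posterior mean converges to
#' \eqn{SEA_C} as n grows.
#'
#' @inheritParams sea
#' @param n_draws Posterior draws (>= 100 recommended).
#' @param seed Integer seed.
#' @param nu0,S0 Inverse-Wishart prior degrees of freedom and scale matrix.
#' @return A \code{niche_ellipse} with an additional \code{SEA_B} vector of
#'   posterior area draws.
#' @export
sea_bayes <- function(d13c, d15n = NULL, n_draws = 4000L, seed = 1L,
                      nu0 = 3, S0 = diag(0.01, 2)) {
  ell <- sea(d13c, d15n)
  if (n_draws < 100L) warning("fewer than 100 posterior draws")
  n <- ell$n
  scale <- S0 + (n - 1) * ell$cov
  df <- nu0 + n - 1
  draws <- with_seed(seed, {
    W <- stats::rWishart(n_draws, df, solve(scale))
    vapply(seq_len(n_draws), function(i) {
      pi * sqrt(det(solve(W[, , i])))
    }, numeric(1))
  })
  ell$SEA_B <- draws
  ell$prior <- list(nu0 = nu0, S0 = S0)
  ell
}

#' Bayesian stable-isotope mixing model
#'
#' Estimates source contributions to consumer diets from two isotope axes.
#' Consumer values are modelled as normal around the contribution-weighted
#' source-plus-fractionation means,
#' \eqn{\mu_j = \sum_k p_k (s_{jk} + f_{jk})}, with variance
#' \eqn{\sum_k p_k^2 (\sigma^2_{jk} + \tau^2_{jk}) + \xi_j^2} per isotope j
#' (source SD \eqn{\sigma}, fractionation SD \eqn{\tau}, residual SD
#' \eqn{\xi}). The prior on the contribution vector p is Dirichlet(1, ..., 1)
#' and residual SDs have a flat prior on (0, 20). Sampling is
#' Metropolis-within-Gibbs: a logistic-normal random walk on p (with the
#' appropriate Jacobian) alternating with log-normal random-walk updates of
#' the residual SDs.
#'
#' @param consumers Data frame with columns \code{d13C} and \code{d15N}.
#' @param sources Data frame with columns \code{name}, \code{mean_d13C},
#'   \code{sd_d13C}, \code{mean_d15N}, \code{sd_d15N} and optionally
#'   \code{frac_d13C}, \code{frac_sd_d13C}, \code{frac_d15N},
#'   \code{frac_sd_d15N}. Missing fractionation columns default to
#'   0.39 +/- 1.3 (d13C) and 3.4 +/- 0.98 (d15N) per trophic step.
#' @param n_iter,burn_in,thin MCMC schedule.
#' @param seed Integer seed.
#' @param step_p,step_sd Initial random-walk proposal scales; both adapt
#'   toward ~30 percent acceptance during burn-in (adaptation stops at the
#'   first kept draw, preserving detailed balance).
#' @return Object of class \code{mixing_posterior}: matrix \code{p} of
#'   contribution draws (columns named by source, each row summing to 1),
#'   matrix \code{resid_sd}, acceptance rates and the configuration. A single
#'   source is allowed as a degenerate case (p = 1 exactly).
#' @export
fit_mixing <- function(consumers, sources, n_iter = 10000L, burn_in = 2000L,
                       thin = 5L, seed = 1L, step_p = 0.3, step_sd = 0.3) {
  x <- as.matrix(consumers[, c("d13C", "d15N")])
  if (!nrow(x)) stop("need at least one consumer")
  K <- nrow(sources)
  if (K < 1L) stop("need at least one source")
  fr <- list(
    mean = cbind(sources$frac_d13C %||% rep(0.39, K),
                 sources$frac_d15N %||% rep(3.4, K)),
    sd = cbind(sources$frac_sd_d13C %||% rep(1.3, K),
               sources$frac_sd_d15N %||% rep(0.98, K)))
  smean <- cbind(sources$mean_d13C, sources$mean_d15N) + fr$mean
  svar <- cbind(sources$sd_d13C, sources$sd_d15N)^2 + fr$sd^2
  n <- nrow(x)
  loglik <- function(p, xi) {
    mu <- colSums(p * smean)            # length 2
    v <- colSums(p^2 * svar) + xi^2
    sum(stats::dnorm(x[, 1], mu[1], sqrt(v[1]), log = TRUE)) +
      sum(stats::dnorm(x[, 2], mu[2], sqrt(v[2]), log = TRUE))
  }
  n_kept <- (n_iter - burn_in) %/% thin
  p_draws <- matrix(NA_real_, n_kept, K,
                    dimnames = list(NULL, as.character(sources$name)))
  sd_draws <- matrix(NA_real_, n_kept, 2,
                     dimnames = list(NULL, c("d13C", "d15N")))
  acc_p <- 0L; acc_sd <- 0L; kept <- 0L
  win_p <- 0L; win_sd <- 0L
  with_seed(seed, {
    p <- rep(1 / K, K)
    xi <- c(1, 1)
    lp <- loglik(p, xi)
    for (it in seq_len(n_iter)) {
      ## adapt proposal scales toward ~30% acceptance during burn-in only
      if (it <= burn_in && it %% 100L == 0L) {
        step_p <- min(5, max(0.02, step_p * exp((win_p / 100 - 0.3))))
        step_sd <- min(5, max(0.02, step_sd * exp((win_sd / 100 - 0.3))))
        win_p <- 0L; win_sd <- 0L
      }
      if (K > 1L) {
        ## logistic-normal RW on p; target includes the Jacobian prod(p)
        z <- log(p[-K] / p[K]) + stats::rnorm(K - 1L, 0, step_p)
        ez <- exp(c(z, 0))
        p_new <- ez / sum(ez)
        lp_new <- loglik(p_new, xi)
        log_ratio <- (lp_new + sum(log(p_new))) - (lp + sum(log(p)))
        if (is.finite(log_ratio) && log(stats::runif(1)) < log_ratio) {
          p <- p_new; lp <- lp_new
          if (it > burn_in) acc_p <- acc_p + 1L
          win_p <- win_p + 1L
        }
      }
      xi_new <- xi * exp(stats::rnorm(2, 0, step_sd))
      if (all(xi_new < 20)) {
        lp_new <- loglik(p, xi_new)
        ## log-normal proposal Jacobian: prior flat on xi, q asymmetry = xi'/xi
        log_ratio <- lp_new - lp + sum(log(xi_new) - log(xi))
        if (is.finite(log_ratio) && log(stats::runif(1)) < log_ratio) {
          xi <- xi_new; lp <- lp_new
          if (it > burn_in) acc_sd <- acc_sd + 1L
          win_sd <- win_sd + 1L
        }
      }
      if (it > burn_in && (it - burn_in) %% thin == 0L) {
        kept <- kept + 1L
        p_draws[kept, ] <- p
        sd_draws[kept, ] <- xi
      }
    }
  })
  acc <- c(p = acc_p / (n_iter - burn_in),
           resid_sd = acc_sd / (n_iter - burn_in))
  if (K > 1L && (acc[["p"]] < 0.1 || acc[["p"]] > 0.6)) {
    warning(sprintf(
      "mixing-model acceptance rate %.2f outside [0.1, 0.6]; check mixing (try adjusting step_p)",
      acc[["p"]]))
  }
  structure(list(p = p_draws, resid_sd = sd_draws, acceptance = acc,
                 n_iter = n_iter, burn_in = burn_in, thin = thin,
                 sources = as.character(sources$name), seed = seed),
            class = "mixing_posterior")
}

#' @export
print.mixing_posterior <- function(x, ...) {
  cat("Bayesian mixing-model posterior\n")
  m <- colMeans(x$p)
  s <- apply(x$p, 2, stats::sd)
  for (k in seq_along(m)) {
    cat(sprintf("  %s: %.3f (sd %.3f)\n", colnames(x$p)[k], m[k], s[k]))
  }
  cat(sprintf("  %d draws, acceptance p %.2f / resid %.2f\n",
              nrow(x$p), x$acceptance[["p"]], x$acceptance[["resid_sd"]]))
  invisible(x)
}

#' Posterior comparison of source contributions
#'
#' Probability that group a's contribution from a source exceeds group b's,
#' computed as the fraction of paired posterior draws (draws are paired by
#' index; the shorter chain length is used).
#'
#' @param a,b \code{mixing_posterior} objects over the same sources.
#' @param source Source name to compare.
#' @return Scalar in [0, 1]; \code{compare_posteriors(a, b, s) +
#'   compare_posteriors(b, a, s) = 1} up to ties.
#' @export
compare_posteriors <- function(a, b, source) {
  stopifnot(inherits(a, "mixing_posterior"), inherits(b, "mixing_posterior"))
  if (!setequal(a$sources, b$sources)) stop("posteriors have different source sets")
  if (!source %in% a$sources) stop("unknown source: ", source)
  m <- min(nrow(a$p), nrow(b$p))
  da <- a$p[seq_len(m), source]
  db <- b$p[seq_len(m), source]
  mean(da > db) + 0.5 * mean(da == db)
}
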