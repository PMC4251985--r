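#' Index of relative importance from stomach contents
#'
#' Computes the percent index of relative importance per prey category for one
#' group of stomachs. With counts and weights pooled across stomachs
#' (the standard IRI convention), for category i:
#' \deqn{IRI_i = (\%N_i + \%W_i)\,\%F_i, \qquad
#'       \%IRI_i = 100\,IRI_i / \sum_j IRI_j}
#' where \eqn{\%N_i} and \eqn{\%W_i} are category percentages of total prey
#' count and weight and \eqn{\%F_i} is the percentage of stomachs containing
#' the category.
#'
#' @param records Data frame with columns \code{fish}, \code{group},
#'   \code{category}, \code{count}, \code{weight} (one row per fish x
#'   category; absent rows count as zero).
#' @param group Group label to tabulate (default: all records).
#' @param nonempty_only If \code{TRUE} (default), \%F is computed over
#'   stomachs containing at least one prey item; otherwise over all stomachs
#'   in the group.
#' @return Data frame with columns \code{category}, \code{pct_N},
#'   \code{pct_W}, \code{pct_F}, \code{IRI}, \code{pct_IRI}; \code{pct_IRI}
#'   sums to 100.
#' @export
iri_table <- function(records, group = NULL, nonempty_only = TRUE) {
  req <- c("fish", "group", "category", "count", "weight")
  if (!all(req %in% names(records))) {
    stop("'records' must have columns ", paste(req, collapse = ", "))
  }
  if (!is.null(group)) records <- records[records$group == group, ]
  if (!nrow(records)) stop("no records for group")
  if (any(records$count < 0 | records$weight < 0)) {
    stop("counts and weights must be >= 0")
  }
  present <- records$count > 0 | records$weight > 0
  full_fish <- unique(records$fish[present])
  if (!length(full_fish)) stop("all stomachs in the group are empty")
  n_stomachs <- if (nonempty_only) length(full_fish) else
    length(unique(records$fish))
  cats <- sort(unique(records$category))
  tot_n <- sum(records$count)
  tot_w <- sum(records$weight)
  out <- data.frame(category = cats, stringsAsFactors = FALSE)
  out$pct_N <- vapply(cats, function(ct)
    100 * sum(records$count[records$category == ct]) / tot_n, numeric(1))
  out$pct_W <- vapply(cats, function(ct)
    100 * sum(records$weight[records$category == ct]) / tot_w, numeric(1))
  out$pct_F <- vapply(cats, function(ct) {
    has <- unique(records$fish[records$category == ct & present])
    100 * length(has) / n_stomachs
  }, numeric(1))
  out$IRI <- (out$pct_N + out$pct_W) * out$pct_F
  out$pct_IRI <- 100 * out$IRI / sum(out$IRI)
  rownames(out) <- NULL
  out
}

#' Schoener proportional similarity index
#'
#' \deqn{PSI = 1 - 0.5 \sum_i |p_i - q_i|}
#' for two diet-proportion vectors over the same categories; 1 for identical
#' diets, 0 for disjoint ones.
#'
#' @param p,q Numeric proportion vectors of equal length, each summing to 1.
#' @return Scalar in [0, 1].
#' @examples
#' psi(c(0.8, 0.2), c(0.2, 0.8))  # 0.4
#' @export
psi <- function(p, q) {
  if (length(p) != length(q)) stop("proportion vectors differ in length")
  if (abs(sum(p) - 1) > 1e-9 || abs(sum(q) - 1) > 1e-9) {
    stop("proportions must each sum to 1")
  }
  1 - 0.5 * sum(abs(p - q))
}

#' Foraging efficacy
#'
#' Prey consumed per strike, \eqn{T_{prey} / (S_V + S_H)}: a [0, 1] measure
#' where larger values mean fewer strikes were needed per prey item consumed.
#' Values above 1 (more prey consumed than strikes recorded) are clamped to 1
#' with a warning to honour the metric's range. Trials without any strike are
#' rejected: the metric is undefined for them (such trials are ended and
#' excluded, keeping only their success flag).
#'
#' @param t_prey Number of prey items consumed (>= 0).
#' @param s_v,s_h Vertical and horizontal strike counts.
#' @return Numeric vector in [0, 1].
#' @export
efficacy <- function(t_prey, s_v, s_h) {
  if (any(t_prey < 0 | s_v < 0 | s_h < 0)) stop("counts must be >= 0")
  strikes <- s_v + s_h
  if (any(strikes == 0)) {
    stop("efficacy is undefined for trials with zero strikes")
  }
  e <- t_prey / strikes
  if (any(e > 1)) {
    warning("efficacy above 1 clamped (more prey consumed than strikes recorded)")
    e <- pmin(e, 1)
  }
  e
}

#' Vertical strike rate
#'
#' Vertical strikes per second over the trial, a foraging-rate measure.
#'
#' @param s_v Vertical strike count.
#' @param duration Trial duration in seconds (default 600, a ten-minute
#'   trial).
#' @return Strikes per second.
#' @export
strike_rate <- function(s_v, duration = 600) {
  if (any(duration <= 0)) stop("duration must be > 0")
  if (any(s_v < 0)) stop("strike counts must be >= 0")
  s_v / duration
}

#' Summarise foraging trials
#'
#' Computes efficacy and strike rate per trial from a trial table, excluding
#' strike-less (failed) trials from efficacy but retaining them in the output
#' with \code{success = FALSE}.
#'
#' @param trials Data frame with columns \code{fish}, \code{form},
#'   \code{s_v}, \code{s_h}, \code{handled}, \code{abandoned}, optionally
#'   \code{duration} (default 600 s).
#' @return The table with added columns \code{t_prey}, \code{success},
#'   \code{efficacy} (NA for unsuccessful trials) and \code{strike_rate}.
#' @export
foraging_summary <- function(trials) {
  if (is.null(trials$duration)) trials$duration <- 600
  trials$t_prey <- trials$handled - trials$abandoned
  if (any(trials$t_prey < 0)) stop("abandoned prey exceeds handled prey")
  trials$success <- (trials$s_v + trials$s_h) > 0
  trials$efficacy <- NA_real_
  ok <- trials$success
  trials$efficacy[ok] <- efficacy(trials$t_prey[ok], trials$s_v[ok],
                                  trials$s_h[ok])
  trials$strike_rate <- strike_rate(trials$s_v, trials$duration)
  trials
}
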