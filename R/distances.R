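#' Per-population allele frequencies
#'
#' Tabulates relative allele-size frequencies for every population x locus
#' cell of a genotype table, counting only observed (non-missing) alleles.
#' Cells with no observed alleles are flagged empty rather than producing
#' 0/0 frequencies.
#'
#' @param g A \code{\link{genotype_table}}.
#' @return An object of class \code{freq_table}: a list with \code{freqs}
#'   (nested list \code{[[population]][[locus]]} of named frequency vectors,
#'   \code{NULL} when the cell is empty), \code{counts} (population x locus
#'   matrix of observed allele counts, i.e. 2N minus missing) and the
#'   population/locus label vectors.
#' @export
allele_frequencies <- function(g) {
  stopifnot(inherits(g, "genotype_table"))
  if (!nrow(g$calls)) stop("empty genotype table")
  pops <- g$populations
  loci <- g$loci$locus
  counts <- matrix(0L, length(pops), length(loci),
                   dimnames = list(pops, loci))
  freqs <- stats::setNames(vector("list", length(pops)), pops)
  for (p in pops) {
    freqs[[p]] <- stats::setNames(vector("list", length(loci)), loci)
    for (loc in loci) {
      sub <- g$calls[g$calls$population == p & g$calls$locus == loc, ]
      alleles <- c(sub$a1, sub$a2)
      alleles <- alleles[!is.na(alleles)]
      counts[p, loc] <- length(alleles)
      if (length(alleles)) {
        tab <- table(alleles)
        freqs[[p]][[loc]] <- stats::setNames(as.numeric(tab) / length(alleles),
                                             names(tab))
      }
    }
  }
  structure(list(freqs = freqs, counts = counts,
                 populations = pops, loci = loci),
            class = "freq_table")
}

#' @export
print.freq_table <- function(x, ...) {
  cat(sprintf("Allele frequency table: %d populations x %d loci (%d empty cells)\n",
              length(x$populations), length(x$loci), sum(x$counts == 0L)))
  invisible(x)
}

## gene identity sum over one or two frequency vectors, aligned on allele size
identity_sums <- function(fa, fb) {
  alleles <- union(names(fa), names(fb))
  xa <- stats::setNames(numeric(length(alleles)), alleles)
  xb <- xa
  xa[names(fa)] <- fa
  xb[names(fb)] <- fb
  c(jx = sum(xa^2), jy = sum(xb^2), jxy = sum(xa * xb))
}

#' Nei's standard genetic distance
#'
#' Computes Nei's D between two populations from allele frequencies:
#' \deqn{D = -\ln\left(J_{XY} / \sqrt{J_X J_Y}\right)}
#' where \eqn{J_X}, \eqn{J_Y} and \eqn{J_{XY}} are arithmetic means across
#' loci of the within- and between-population gene identities
#' \eqn{\sum x_i^2}, \eqn{\sum y_i^2} and \eqn{\sum x_i y_i}. Loci with no
#' observed alleles in either population are excluded pairwise. When no
#' alleles are shared at any locus (\eqn{J_{XY} = 0}) the distance is
#' \code{Inf}, reported with a warning rather than an error.
#'
#' @param f A \code{freq_table} from \code{\link{allele_frequencies}}.
#' @param popA,popB Population labels.
#' @return Non-negative numeric scalar (possibly \code{Inf}).
#' @export
nei_distance <- function(f, popA, popB) {
  stopifnot(inherits(f, "freq_table"))
  if (!all(c(popA, popB) %in% f$populations)) {
    stop("unknown population(s): ",
         paste(setdiff(c(popA, popB), f$populations), collapse = ", "))
  }
  shared <- f$loci[f$counts[popA, f$loci] > 0L & f$counts[popB, f$loci] > 0L]
  if (!length(shared)) stop("no locus with observed alleles in both populations")
  js <- vapply(shared, function(loc) {
    identity_sums(f$freqs[[popA]][[loc]], f$freqs[[popB]][[loc]])
  }, numeric(3))
  jx <- mean(js["jx", ]); jy <- mean(js["jy", ]); jxy <- mean(js["jxy", ])
  if (jxy <= 0) {
    warning("no shared alleles between '", popA, "' and '", popB,
            "': Nei's D is infinite")
    return(Inf)
  }
  max(0, -log(jxy / sqrt(jx * jy)))
}

#' Goldstein's delta-mu-squared distance
#'
#' Mean across loci of the squared difference in mean allele size (in repeat
#' units) between two populations, the stepwise-mutation-model distance whose
#' expectation grows linearly (as \eqn{2\mu t}) with divergence time. Loci
#' lacking observed alleles in either population are excluded pairwise.
#'
#' @param g A \code{\link{genotype_table}}.
#' @param popA,popB Population labels.
#' @return Non-negative numeric scalar.
#' @export
delta_mu_squared <- function(g, popA, popB) {
  stopifnot(inherits(g, "genotype_table"))
  if (!all(c(popA, popB) %in% g$populations)) {
    stop("unknown population(s): ",
         paste(setdiff(c(popA, popB), g$populations), collapse = ", "))
  }
  mean_size <- function(pop, loc) {
    sub <- g$calls[g$calls$population == pop & g$calls$locus == loc, ]
    a <- c(sub$a1, sub$a2)
    a <- a[!is.na(a)]
    if (!length(a)) NA_real_ else mean(a)
  }
  d2 <- vapply(g$loci$locus, function(loc) {
    (mean_size(popA, loc) - mean_size(popB, loc))^2
  }, numeric(1))
  d2 <- d2[!is.na(d2)]
  if (!length(d2)) stop("no locus with observed alleles in both populations")
  mean(d2)
}

#' Pairwise genetic distance matrix
#'
#' Computes all pairwise distances between populations under the chosen
#' metric. Infinite Nei's D values (no shared alleles) are kept in the matrix
#' and flagged via the \code{"has_infinite"} attribute so that downstream
#' consumers (e.g. \code{\link{upgma}}) can refuse them loudly.
#'
#' @param g A \code{\link{genotype_table}}.
#' @param metric \code{"nei_d"} or \code{"delta_mu2"}.
#' @return A symmetric numeric matrix with zero diagonal, population labels as
#'   dimnames, and attributes \code{metric} and \code{has_infinite}.
#' @export
distance_matrix <- function(g, metric = c("nei_d", "delta_mu2")) {
  metric <- match.arg(metric)
  stopifnot(inherits(g, "genotype_table"))
  pops <- g$populations
  if (length(pops) < 2L) stop("need at least 2 populations")
  f <- if (metric == "nei_d") allele_frequencies(g) else NULL
  n <- length(pops)
  d <- matrix(0, n, n, dimnames = list(pops, pops))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      v <- if (metric == "nei_d") {
        nei_distance(f, pops[i], pops[j])
      } else {
        delta_mu_squared(g, pops[i], pops[j])
      }
      d[i, j] <- v
      d[j, i] <- v
    }
  }
  attr(d, "metric") <- metric
  attr(d, "has_infinite") <- any(is.infinite(d))
  d
}

#' Locus-bootstrap replicate distance matrices
#'
#' Resamples loci with replacement (the locus is the resampling unit, the
#' convention used for microsatellite tree support) and recomputes the full
#' distance matrix for each replicate. Replicate \code{i} is generated under
#' the derived seed \code{seed + i}, so runs are reproducible and each
#' replicate is independently replayable.
#'
#' @param g A \code{\link{genotype_table}}.
#' @param metric \code{"nei_d"} or \code{"delta_mu2"}.
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Integer seed.
#' @return List of distance matrices; each carries the resampled locus indices
#'   as attribute \code{"locus_indices"}.
#' @export
bootstrap_distances <- function(g, metric = c("nei_d", "delta_mu2"),
                                n_reps = 200L, seed = 1L) {
  metric <- match.arg(metric)
  stopifnot(inherits(g, "genotype_table"))
  if (n_reps < 1L) stop("'n_reps' must be >= 1")
  loci <- g$loci$locus
  if (length(loci) == 1L) {
    warning("single-locus table: bootstrap over loci is degenerate")
  }
  lapply(seq_len(n_reps), function(r) {
    idx <- with_seed(child_seed(seed, r),
                     sample.int(length(loci), replace = TRUE))
    gb <- resample_loci(g, idx)
    m <- distance_matrix(gb, metric)
    attr(m, "locus_indices") <- idx
    m
  })
}

## build a genotype table whose loci are g's loci at positions idx
## (duplicates renamed so the table remains valid)
resample_loci <- function(g, idx) {
  loci <- g$loci$locus[idx]
  new_names <- make.unique(loci, sep = ".rep")
  parts <- lapply(seq_along(idx), function(k) {
    sub <- g$calls[g$calls$locus == loci[k], ]
    sub$locus <- new_names[k]
    sub
  })
  new_loci <- data.frame(locus = new_names,
                         repeat_length = g$loci$repeat_length[idx],
                         stringsAsFactors = FALSE)
  genotype_table(do.call(rbind, parts), new_loci)
}

#' Write a distance matrix as labelled square CSV
#'
#' @param d Matrix from \code{\link{distance_matrix}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_distance_matrix <- function(d, path) {
  utils::write.csv(as.data.frame(d), path, row.names = TRUE)
  invisible(path)
}
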