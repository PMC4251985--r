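#' Microsatellite genotype tables
#'
#' A \code{genotype_table} holds diploid allele calls for a set of individuals
#' typed at a panel of microsatellite loci, together with the per-locus repeat
#' unit length. Allele sizes are stored in repeat units; the CSV reader
#' converts from base pairs on load. Missing calls are kept as explicit
#' \code{NA} pairs so that loci are never silently dropped.
#'
#' @param calls Data frame with columns \code{population}, \code{individual},
#'   \code{locus}, \code{a1}, \code{a2}. Allele sizes are positive integers in
#'   repeat units; both \code{a1} and \code{a2} are \code{NA} for a missing
#'   call.
#' @param loci Data frame with columns \code{locus} and \code{repeat_length}
#'   (integer base pairs per repeat unit).
#' @return An object of class \code{genotype_table} with elements
#'   \code{calls}, \code{loci} and \code{populations}.
#' @examples
#' calls <- data.frame(
#'   population = c("A", "A", "B", "B"),
#'   individual = c("a1", "a2", "b1", "b2"),
#'   locus = "L1", a1 = c(10L, 10L, 12L, 12L), a2 = c(10L, 11L, 12L, 13L)
#' )
#' g <- genotype_table(calls, data.frame(locus = "L1", repeat_length = 4L))
#' g
#' @export
genotype_table <- function(calls, loci) {
  required <- c("population", "individual", "locus", "a1", "a2")
  if (!all(required %in% names(calls))) {
    stop("'calls' must have columns ", paste(required, collapse = ", "))
  }
  calls <- as.data.frame(calls)[required]
  calls$population <- as.character(calls$population)
  calls$individual <- as.character(calls$individual)
  calls$locus <- as.character(calls$locus)
  calls$a1 <- as.integer(calls$a1)
  calls$a2 <- as.integer(calls$a2)
  loci <- as.data.frame(loci)
  if (!all(c("locus", "repeat_length") %in% names(loci))) {
    stop("'loci' must have columns locus, repeat_length")
  }
  loci$locus <- as.character(loci$locus)
  loci$repeat_length <- as.integer(loci$repeat_length)
  if (anyDuplicated(loci$locus)) stop("duplicate locus in 'loci'")
  unknown <- setdiff(unique(calls$locus), loci$locus)
  if (length(unknown)) {
    stop("calls refer to loci absent from 'loci': ",
         paste(unknown, collapse = ", "))
  }
  half <- xor(is.na(calls$a1), is.na(calls$a2))
  if (any(half)) stop("half-missing genotype calls (one allele NA) found")
  obs <- c(calls$a1, calls$a2)
  if (any(!is.na(obs) & obs <= 0L)) stop("allele sizes must be positive")
  ## each individual belongs to exactly one population
  pop_of <- tapply(calls$population, calls$individual,
                   function(p) length(unique(p)))
  if (any(pop_of > 1L)) {
    stop("individual(s) assigned to more than one population: ",
         paste(names(pop_of)[pop_of > 1L], collapse = ", "))
  }
  structure(
    list(calls = calls, loci = loci,
         populations = unique(calls$population)),
    class = "genotype_table"
  )
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("Microsatellite genotype table\n")
  cat(sprintf("  %d individuals, %d populations, %d loci\n",
              length(unique(x$calls$individual)),
              length(x$populations), nrow(x$loci)))
  n_missing <- sum(is.na(x$calls$a1))
  cat(sprintf("  %d of %d calls missing\n", n_missing, nrow(x$calls)))
  invisible(x)
}

#' Read microsatellite genotypes
#'
#' Reads a diploid genotype file into a \code{\link{genotype_table}}. Two
#' dialects are supported. The \code{"csv"} dialect expects columns
#' \code{population}, \code{individual}, then one column per locus containing
#' \code{"a1/a2"} allele sizes in base pairs (empty or \code{NA} for missing);
#' a sidecar table maps each locus to its repeat-unit length in base pairs,
#' used to convert sizes to repeat units on load. The \code{"genepop"} dialect
#' reads a GenePop-like file (title line, one locus name per line, \code{Pop}
#' separators, then \code{id , 090090 120120 ...} rows with concatenated
#' 2- or 3-digit alleles, \code{000}/\code{00} meaning missing); alleles are
#' taken to be already in repeat units unless \code{loci} is supplied.
#'
#' @param path Path to the genotype file.
#' @param dialect Either \code{"csv"} or \code{"genepop"}.
#' @param loci For \code{"csv"}: a data frame with columns \code{locus},
#'   \code{repeat_length}, or a path to a CSV holding the same. Optional for
#'   \code{"genepop"} (defaults to repeat length 1, i.e. sizes already in
#'   repeat units).
#' @return A \code{\link{genotype_table}}.
#' @seealso \code{\link{write_genotypes}}
#' @export
read_genotypes <- function(path, dialect = c("csv", "genepop"), loci = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.character(loci) && length(loci) == 1L) {
    loci <- utils::read.csv(loci, stringsAsFactors = FALSE)
  }
  if (dialect == "csv") read_genotypes_csv(path, loci) else
    read_genotypes_genepop(path, loci)
}

read_genotypes_csv <- function(path, loci) {
  if (is.null(loci)) stop("'loci' sidecar (locus, repeat_length) is required for the csv dialect")
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  if (!all(c("population", "individual") %in% names(raw))) {
    stop("csv dialect requires 'population' and 'individual' columns")
  }
  locus_cols <- setdiff(names(raw), c("population", "individual"))
  if (!length(locus_cols)) stop("no locus columns found")
  if (anyDuplicated(raw$individual)) {
    stop("duplicate individual ID(s): ",
         paste(unique(raw$individual[duplicated(raw$individual)]), collapse = ", "))
  }
  loci <- as.data.frame(loci)
  loci$locus <- as.character(loci$locus)
  missing_rl <- setdiff(locus_cols, loci$locus)
  if (length(missing_rl)) {
    stop("no repeat length for locus/loci: ", paste(missing_rl, collapse = ", "))
  }
  rl <- stats::setNames(as.integer(loci$repeat_length), loci$locus)
  out <- vector("list", length(locus_cols))
  for (j in seq_along(locus_cols)) {
    loc <- locus_cols[j]
    field <- raw[[loc]]
    a1 <- rep(NA_integer_, nrow(raw))
    a2 <- rep(NA_integer_, nrow(raw))
    for (i in seq_len(nrow(raw))) {
      f <- trimws(field[i])
      if (f == "" || toupper(f) == "NA") next
      parts <- strsplit(f, "/", fixed = TRUE)[[1]]
      sizes <- suppressWarnings(as.numeric(parts))
      if (length(parts) != 2L || any(is.na(sizes)) || any(sizes <= 0)) {
        stop(sprintf(
          "parse error at line %d (individual '%s', locus '%s'): cannot read allele field '%s'",
          i + 1L, raw$individual[i], loc, field[i]))
      }
      a1[i] <- as.integer(round(sizes[1] / rl[[loc]]))
      a2[i] <- as.integer(round(sizes[2] / rl[[loc]]))
    }
    out[[j]] <- data.frame(
      population = raw$population, individual = raw$individual,
      locus = loc, a1 = a1, a2 = a2, stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, out)
  genotype_table(calls, loci[loci$locus %in% locus_cols, ])
}

read_genotypes_genepop <- function(path, loci) {
  lines <- readLines(path)
  lines <- lines[trimws(lines) != ""]
  if (length(lines) < 3L) stop("genepop file too short")
  body <- lines[-1L]                      # drop title
  pop_idx <- grep("^\\s*pop\\s*$", body, ignore.case = TRUE)
  if (!length(pop_idx)) stop("no 'Pop' separator found")
  locus_lines <- body[seq_len(pop_idx[1] - 1L)]
  locus_names <- trimws(unlist(strsplit(locus_lines, ",")))
  locus_names <- locus_names[locus_names != ""]
  if (is.null(loci)) {
    loci <- data.frame(locus = locus_names, repeat_length = 1L,
                       stringsAsFactors = FALSE)
  }
  rl <- stats::setNames(as.integer(loci$repeat_length), as.character(loci$locus))
  rows <- list()
  pop_no <- 0L
  for (k in seq_along(body)) {
    if (k %in% pop_idx) { pop_no <- pop_no + 1L; next }
    if (k < pop_idx[1]) next
    ln <- body[k]
    halves <- strsplit(ln, ",")[[1]]
    if (length(halves) < 2L) {
      stop(sprintf("parse error at line %d: expected 'id , alleles'", k + 1L))
    }
    id <- trimws(halves[1])
    fields <- strsplit(trimws(paste(halves[-1], collapse = ",")), "\\s+")[[1]]
    if (length(fields) != length(locus_names)) {
      stop(sprintf("parse error at line %d: %d allele fields for %d loci",
                   k + 1L, length(fields), length(locus_names)))
    }
    w <- nchar(fields[1]) / 2
    if (!w %in% c(2, 3)) {
      stop(sprintf("parse error at line %d: allele field '%s' not 4 or 6 digits",
                   k + 1L, fields[1]))
    }
    a1 <- suppressWarnings(as.integer(substr(fields, 1, w)))
    a2 <- suppressWarnings(as.integer(substr(fields, w + 1, 2 * w)))
    if (any(is.na(a1)) || any(is.na(a2))) {
      stop(sprintf("parse error at line %d: non-numeric allele field", k + 1L))
    }
    a1[a1 == 0L] <- NA_integer_
    a2[a2 == 0L] <- NA_integer_
    ## a half-missing call (one allele coded 000) is treated as fully missing
    miss <- is.na(a1) | is.na(a2)
    a1[miss] <- NA_integer_
    a2[miss] <- NA_integer_
    a1 <- as.integer(round(a1 / rl[locus_names]))
    a2 <- as.integer(round(a2 / rl[locus_names]))
    rows[[length(rows) + 1L]] <- data.frame(
      population = paste0("pop", pop_no), individual = id,
      locus = locus_names, a1 = a1, a2 = a2, stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, rows)
  if (anyDuplicated(unique(calls[c("population", "individual")])$individual)) {
    stop("duplicate individual ID across populations")
  }
  genotype_table(calls, loci)
}

#' Write a genotype table to CSV
#'
#' Writes the wide CSV dialect read by \code{\link{read_genotypes}} (allele
#' sizes in base pairs as \code{"a1/a2"}) plus a sidecar locus table.
#'
#' @param g A \code{\link{genotype_table}}.
#' @param path Output CSV path for the genotype matrix.
#' @param loci_path Output CSV path for the locus/repeat-length sidecar.
#' @return Invisibly, \code{path}.
#' @export
write_genotypes <- function(g, path, loci_path) {
  stopifnot(inherits(g, "genotype_table"))
  rl <- stats::setNames(g$loci$repeat_length, g$loci$locus)
  inds <- unique(g$calls[c("population", "individual")])
  wide <- data.frame(population = inds$population,
                     individual = inds$individual,
                     stringsAsFactors = FALSE, check.names = FALSE)
  for (loc in g$loci$locus) {
    sub <- g$calls[g$calls$locus == loc, ]
    m <- match(inds$individual, sub$individual)
    a1 <- sub$a1[m] * rl[[loc]]
    a2 <- sub$a2[m] * rl[[loc]]
    wide[[loc]] <- ifelse(is.na(a1), "", paste0(a1, "/", a2))
  }
  utils::write.csv(wide, path, row.names = FALSE)
  utils::write.csv(g$loci, loci_path, row.names = FALSE)
  invisible(path)
}
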