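#' Small exact tandem-repeat detection around an indel
#'
#' An indel is deemed to lie in a repeat region when the indel allele, or a
#' substring of it, is tiled as exact tandem copies across the allele itself
#' and its contiguous flanking sequence. Candidate repeat units are all
#' substrings of the allele; for each unit every maximal tandem run in
#' `left_flank + indel_seq + right_flank` that touches the allele is scored.
#' The winning call is the qualifying run with the greatest total length
#' (period x copies); ties go to the smallest period, so a mononucleotide
#' decomposition such as (C)5 beats (CCC)1 or (CC)2 on the same bases.
#'
#' A run qualifies when it has at least 2 copies and its total length reaches
#' the period-specific minimum: 4 bases for mononucleotide repeats, 6 for
#' trinucleotide repeats, and `max(4, 2 * period)` in general.
#'
#' @param indel_seq the inserted or deleted bases (non-empty).
#' @param left_flank reference bases immediately 5' of the indel site (may be "").
#' @param right_flank reference bases immediately 3' of the indel site (may be "").
#' @return an object of class `repeat_call`: list with `is_repeat`, `unit`,
#'   `period`, `copies`, `total_length`. When nothing qualifies, `is_repeat`
#'   is `FALSE`, `copies` and `total_length` are 0 and `unit` is `NA`.
#' @examples
#' find_repeat("CAT", "ctcctc", "catctg")  # (CAT)2
#' find_repeat("CCC", "atcgg", "ccacc")    # (C)5
#' @export
find_repeat <- function(indel_seq, left_flank = "", right_flank = "") {
  if (!nzchar(indel_seq)) stop("indel_seq must be non-empty")
  s <- toupper(paste0(left_flank, indel_seq, right_flank))
  a0 <- nchar(left_flank) + 1L            # allele occupies a0 .. a1 in s
  a1 <- nchar(left_flank) + nchar(indel_seq)
  allele <- toupper(indel_seq)

  units <- unique(unlist(lapply(seq_len(nchar(allele)), function(p) {
    vapply(seq_len(nchar(allele) - p + 1L),
           function(i) substr(allele, i, i + p - 1L), character(1))
  })))

  best <- NULL
  for (u in units) {
    p <- nchar(u)
    runs <- tandem_runs(s, u)
    for (r in seq_len(nrow(runs))) {
      st <- runs$start[r]; k <- runs$copies[r]
      en <- st + p * k - 1L
      if (en < a0 || st > a1) next            # run does not touch the allele
      if (k < 2L || p * k < min_repeat_length(p)) next
      cand <- list(unit = u, period = p, copies = k, total_length = p * k)
      if (is.null(best) ||
          cand$total_length > best$total_length ||
          (cand$total_length == best$total_length && cand$period < best$period)) {
        best <- cand
      }
    }
  }

  if (is.null(best)) {
    call <- list(is_repeat = FALSE, unit = NA_character_, period = 0L,
                 copies = 0L, total_length = 0L)
  } else {
    call <- c(list(is_repeat = TRUE), best)
  }
  structure(call, class = "repeat_call")
}

#' @export
print.repeat_call <- function(x, ...) {
  if (x$is_repeat) {
    cat(sprintf("repeat (%s)%d: period %d, total length %d\n",
                x$unit, x$copies, x$period, x$total_length))
  } else {
    cat("no repeat\n")
  }
  invisible(x)
}

# Minimum total repeat length required to call a repeat of the given period.
# Anchored at 4 for period 1 and 6 for period 3; otherwise at least two full
# copies and at least 4 bases.
min_repeat_length <- function(period) {
  max(4L, 2L * as.integer(period))
}

# All maximal tandem runs of unit `u` in string `s`, as a data.frame of
# (start, copies). A run is maximal: it is not preceded by another copy of
# `u` at distance period, and extends as far right as exact copies continue.
tandem_runs <- function(s, u) {
  p <- nchar(u); n <- nchar(s)
  if (p > n) return(data.frame(start = integer(), copies = integer()))
  # positions where u occurs
  occ <- integer(0)
  for (i in seq_len(n - p + 1L)) {
    if (substr(s, i, i + p - 1L) == u) occ <- c(occ, i)
  }
  if (!length(occ)) return(data.frame(start = integer(), copies = integer()))
  occset <- rep(FALSE, n); occset[occ] <- TRUE
  starts <- integer(0); copies <- integer(0)
  for (i in occ) {
    if (i - p >= 1L && occset[i - p]) next  # not run-maximal on the left
    k <- 1L
    while (i + k * p <= n - p + 1L && occset[i + k * p]) k <- k + 1L
    starts <- c(starts, i); copies <- c(copies, k)
  }
  data.frame(start = starts, copies = copies)
}

#' Left-normalize an indel
#'
#' Shifts the indel to the leftmost genomic position that produces an
#' identical alternate sequence. Inside a tandem repeat this moves the indel
#' to the repeat's 5' edge (the consistent-coordinate convention every
#' downstream feature assumes); outside repeats, when no shift preserves the
#' mutant sequence, the indel is returned unchanged apart from the
#' `normalized` flag. Idempotent.
#'
#' @param x an `indel`.
#' @param reference a `ref_store` covering the region 5' of the indel (the
#'   shift stops at the stored sequence boundary).
#' @return the normalized `indel` (`normalized = TRUE`).
#' @export
left_normalize <- function(x, reference) {
  stopifnot(inherits(x, "indel"), inherits(reference, "ref_store"))
  b <- ref_bounds(reference, x$chrom)
  pos <- x$pos
  allele <- indel_allele(x)
  len <- nchar(allele)
  if (x$kind == "deletion") {
    obs <- ref_seq(reference, x$chrom, pos, pos + len - 1L)
    if (obs != allele) {
      stop("deleted allele does not match reference at ", x$chrom, ":", pos)
    }
  }
  # shifting one base left is valid iff the base 5' of the indel equals the
  # allele's last base; the allele then rotates right by one
  while (pos > b[1]) {
    prev <- ref_seq(reference, x$chrom, pos - 1L, pos - 1L)
    last <- substr(allele, len, len)
    if (prev != last) break
    allele <- paste0(last, substr(allele, 1, len - 1L))
    pos <- pos - 1L
  }
  if (x$kind == "insertion") {
    indel(x$chrom, pos, alt_allele = allele, normalized = TRUE)
  } else {
    indel(x$chrom, pos, ref_allele = allele, normalized = TRUE)
  }
}

#' Repeat context of an indel against the reference
#'
#' Convenience wrapper: pulls the flanking reference sequence around the
#' indel site and runs [find_repeat()]. For a deletion the right flank starts
#' after the deleted bases; for an insertion it starts at the insertion point.
#'
#' @param x an `indel`.
#' @param reference a `ref_store`.
#' @param window flank length in bases searched on each side (default 50).
#' @return a `repeat_call`.
#' @export
repeat_context <- function(x, reference, window = 50L) {
  stopifnot(inherits(x, "indel"))
  left <- ref_seq_clip(reference, x$chrom, x$pos - window, x$pos - 1L)
  rstart <- if (x$kind == "deletion") x$pos + x$length else x$pos
  right <- ref_seq_clip(reference, x$chrom, rstart, rstart + window - 1L)
  find_repeat(indel_allele(x), left, right)
}

#' Summarise repeat calls: total-length and period/copies distribution
#'
#' Tabulates a collection of repeat calls the way repeat landscapes are
#' usually reported: counts per (period, copies) cell, counts per total
#' length (period x copies), and the fraction of repeat periods divisible
#' by 3 (in coding sequence, a period-3 repeat is a repeating amino acid).
#' Non-repeat calls are excluded from the tables but counted.
#'
#' @param calls list of `repeat_call` objects.
#' @return list with `by_period_copies` (data.frame period, copies, count),
#'   `by_total_length` (data.frame total_length, count),
#'   `fraction_period_div3`, `n_repeat`, `n_total`.
#' @export
repeat_length_distribution <- function(calls) {
  if (!length(calls)) stop("no repeat calls supplied")
  stopifnot(all(vapply(calls, inherits, logical(1), "repeat_call")))
  rep_calls <- Filter(function(c) isTRUE(c$is_repeat), calls)
  if (!length(rep_calls)) stop("no repeat-positive calls to summarise")
  period <- vapply(rep_calls, `[[`, integer(1), "period")
  copies <- vapply(rep_calls, `[[`, integer(1), "copies")
  total <- vapply(rep_calls, `[[`, integer(1), "total_length")
  pc <- as.data.frame(table(period = period, copies = copies),
                      stringsAsFactors = FALSE)
  pc <- pc[pc$Freq > 0, ]
  pc$period <- as.integer(pc$period); pc$copies <- as.integer(pc$copies)
  names(pc)[3] <- "count"
  tl <- as.data.frame(table(total_length = total), stringsAsFactors = FALSE)
  tl$total_length <- as.integer(tl$total_length)
  names(tl)[2] <- "count"
  list(by_period_copies = pc[order(pc$period, pc$copies), ],
       by_total_length = tl[order(tl$total_length), ],
       fraction_period_div3 = mean(period %% 3L == 0L),
       n_repeat = length(rep_calls), n_total = length(calls))
}
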