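#' Interval annotation tracks (protein domains, disorder regions)
#'
#' Loads a BED-like file into a sorted interval track. Two coordinate spaces
#' are supported: `"genome"` (column 1 = chromosome) and `"protein"`
#' (column 1 = protein/transcript id, columns 2-3 = residue interval,
#' 0-based half-open on disk as is conventional for BED). Internally all
#' intervals are 1-based inclusive, matching the indel convention, and are
#' held as a plain sorted table so point/overlap queries stay cheap in tight
#' per-indel loops.
#'
#' @param path BED file with at least 3 columns.
#' @param coordinate_space "protein" or "genome".
#' @param name track label (defaults to the file name).
#' @return object of class `interval_track`.
#' @export
load_interval_track <- function(path, coordinate_space = c("protein", "genome"),
                                name = basename(path)) {
  coordinate_space <- match.arg(coordinate_space)
  if (file.exists(path) && !any(nzchar(readLines(path, warn = FALSE)))) {
    # empty track file: queries all return none
    return(interval_track(data.frame(seq = character(), start = integer(),
                                     end = integer()),
                          coordinate_space, name = name))
  }
  gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                 error = function(e) stop("failed to parse BED file ", path,
                                          ": ", conditionMessage(e)))
  if (any(GenomicRanges::width(gr) < 1L)) {
    stop("interval with end <= start in ", path)
  }
  interval_track(data.frame(seq = as.character(GenomicRanges::seqnames(gr)),
                            start = GenomicRanges::start(gr),
                            end = GenomicRanges::end(gr),
                            stringsAsFactors = FALSE),
                 coordinate_space, name = name)
}

#' Build an interval track from a data.frame
#'
#' @param df data.frame with `seq` (chromosome or protein id), `start`,
#'   `end` — 1-based inclusive.
#' @inheritParams load_interval_track
#' @export
interval_track <- function(df, coordinate_space = c("protein", "genome"),
                           name = "track") {
  coordinate_space <- match.arg(coordinate_space)
  stopifnot(all(c("seq", "start", "end") %in% names(df)))
  if (nrow(df) && any(df$end < df$start)) stop("interval with end < start")
  df <- df[order(df$seq, df$start, df$end), c("seq", "start", "end"),
           drop = FALSE]
  rownames(df) <- NULL
  structure(list(name = name, df = df, coordinate_space = coordinate_space),
            class = "interval_track")
}

#' @export
print.interval_track <- function(x, ...) {
  cat(sprintf("interval_track '%s' (%s space): %d interval(s) on %d sequence(s)\n",
              x$name, x$coordinate_space, nrow(x$df),
              length(unique(x$df$seq))))
  invisible(x)
}

#' Fraction of a protein's domain instances hit by a residue span
#'
#' Counts the domain intervals annotated on the protein that overlap the
#' affected span, divided by the total number of domain intervals on that
#' protein. A protein with no annotated domains scores 0 (not missing), so
#' "no domain affected" rules fire for domain-less proteins.
#'
#' @param span integer `c(start, end)`, 1-based inclusive residue interval.
#' @param protein_id protein (transcript) identifier.
#' @param domains an `interval_track` in protein space.
#' @return fraction in [0, 1].
#' @export
fraction_domains_affected <- function(span, protein_id, domains) {
  stopifnot(inherits(domains, "interval_track"),
            domains$coordinate_space == "protein")
  d <- domains$df
  on_prot <- d$seq == protein_id
  n <- sum(on_prot)
  if (n == 0L) return(0)
  hit <- on_prot & d$start <= span[2] & d$end >= span[1]
  sum(hit) / n
}

#' Is a residue span (mostly) inside annotated disorder?
#'
#' TRUE when strictly more than half of the span's residues fall inside
#' disorder intervals (for a single-residue span this is plain membership).
#'
#' @inheritParams fraction_domains_affected
#' @param disorder an `interval_track` in protein space.
#' @export
in_disordered_region <- function(span, protein_id, disorder) {
  stopifnot(inherits(disorder, "interval_track"),
            disorder$coordinate_space == "protein")
  d <- disorder$df
  on_prot <- which(d$seq == protein_id)
  if (!length(on_prot)) return(FALSE)
  residues <- span[1]:span[2]
  covered <- vapply(residues, function(r) {
    any(d$start[on_prot] <= r & d$end[on_prot] >= r)
  }, logical(1))
  sum(covered) / length(residues) > 0.5
}

#' Per-base conservation score track
#'
#' Reads a bedGraph or wiggle file of per-base scores (PhyloP-like). Missing
#' positions stay distinguishable from score 0: queries off the track return
#' `NA`. Single-base records (the per-base case) are indexed for constant-
#' time lookup; multi-base intervals fall back to a scan.
#'
#' @param path bedGraph or wig file.
#' @param format "bedGraph" (default) or "wig".
#' @return object of class `score_track`.
#' @export
load_score_track <- function(path, format = c("bedGraph", "wig")) {
  format <- match.arg(format)
  gr <- tryCatch(rtracklayer::import(path, format = format),
                 error = function(e) stop("failed to parse ", format, " file ",
                                          path, ": ", conditionMessage(e)))
  df <- data.frame(seq = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   score = gr$score, stringsAsFactors = FALSE)
  score_track(df, name = basename(path))
}

#' Build a score track from a data.frame (`seq`, `start`, `end`, `score`)
#' @param df scored intervals, 1-based inclusive.
#' @param name track label.
#' @export
score_track <- function(df, name = "scores") {
  stopifnot(all(c("seq", "start", "end", "score") %in% names(df)))
  base_idx <- new.env(parent = emptyenv())
  single <- df$start == df$end
  if (any(single)) {
    keys <- paste0(df$seq[single], ":", df$start[single])
    vals <- df$score[single]
    for (i in seq_along(keys)) assign(keys[i], vals[i], envir = base_idx)
  }
  structure(list(name = name, df = df, base_idx = base_idx,
                 all_single = all(single)),
            class = "score_track")
}

#' @export
print.score_track <- function(x, ...) {
  cat(sprintf("score_track '%s': %d scored interval(s)\n", x$name,
              nrow(x$df)))
  invisible(x)
}

#' Score at a single genomic base
#'
#' @param track a `score_track`.
#' @param chrom chromosome.
#' @param pos 1-based position.
#' @return numeric score, or `NA` when the position is not scored.
#' @export
score_at <- function(track, chrom, pos) {
  stopifnot(inherits(track, "score_track"))
  if (pos < 1L) return(NA_real_)
  key <- paste0(chrom, ":", pos)
  v <- get0(key, envir = track$base_idx, ifnotfound = NULL)
  if (!is.null(v)) return(v)
  if (track$all_single) return(NA_real_)
  d <- track$df
  hit <- which(d$seq == chrom & d$start <= pos & d$end >= pos)
  if (!length(hit)) return(NA_real_)
  d$score[hit[1]]
}

#' Conservation of the base 5' of a (normalized) indel
#'
#' The classifier's conservation feature is the score of the DNA base
#' immediately to the left of the allele, looked up after left-normalization
#' (normalization first, so all equivalent placements of a repeat-region
#' indel query the same base). Positions off the chromosome start or absent
#' from the track yield `NA`, never a silent 0.
#'
#' @param x a left-normalized `indel`.
#' @param cons a `score_track`.
#' @export
left_flank_conservation <- function(x, cons) {
  stopifnot(inherits(x, "indel"))
  if (!x$normalized) {
    stop("indel must be left-normalized before conservation lookup")
  }
  score_at(cons, x$chrom, x$pos - 1L)
}
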