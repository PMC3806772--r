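#' Reference sequence store
#'
#' Holds chromosome sequences for base-level lookup. Each chromosome may carry
#' an offset: the stored sequence then covers genomic positions
#' `offset + 1 .. offset + nchar(seq)`. This makes it possible to work with a
#' short sequence excised from a real coordinate system (e.g. a 100 bp window
#' around chr12:132,547,088) without materialising the whole chromosome.
#'
#' @param sequences named character vector or `Biostrings::DNAStringSet`,
#'   one element per chromosome.
#' @param offsets optional named integer vector of 0-based offsets (bases
#'   preceding the stored sequence); chromosomes not named get offset 0.
#' @return an object of class `ref_store`.
#' @export
ref_store <- function(sequences, offsets = NULL) {
  if (inherits(sequences, "DNAStringSet")) {
    sequences <- as.character(sequences)
  }
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    stop("reference sequences must be named by chromosome")
  }
  # FASTA headers may carry descriptions after whitespace; keep the first token
  names(sequences) <- sub("\\s.*$", "", names(sequences))
  seqs <- toupper(sequences)
  off <- stats::setNames(rep(0L, length(seqs)), names(seqs))
  if (!is.null(offsets)) {
    bad <- setdiff(names(offsets), names(seqs))
    if (length(bad)) stop("offset given for unknown chromosome: ", bad[1])
    off[names(offsets)] <- as.integer(offsets)
  }
  structure(list(seqs = seqs, offsets = off), class = "ref_store")
}

#' Read a reference FASTA into a `ref_store`
#'
#' @param path FASTA file (optionally indexed; read in full).
#' @param offsets see [ref_store()].
#' @export
read_reference <- function(path, offsets = NULL) {
  ref_store(Biostrings::readDNAStringSet(path), offsets = offsets)
}

#' @export
print.ref_store <- function(x, ...) {
  cat("ref_store with", length(x$seqs), "sequence(s):\n")
  for (nm in names(x$seqs)) {
    cat(sprintf("  %s: %d bp, positions %d-%d\n", nm, nchar(x$seqs[[nm]]),
                x$offsets[[nm]] + 1L,
                x$offsets[[nm]] + nchar(x$seqs[[nm]])))
  }
  invisible(x)
}

ref_bounds <- function(ref, chrom) {
  if (!chrom %in% names(ref$seqs)) {
    stop("chromosome not in reference: ", chrom)
  }
  off <- ref$offsets[[chrom]]
  c(off + 1L, off + nchar(ref$seqs[[chrom]]))
}

#' Extract reference bases
#'
#' @param ref a `ref_store`.
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive genomic positions.
#' @return upper-case base string.
#' @export
ref_seq <- function(ref, chrom, start, end) {
  stopifnot(inherits(ref, "ref_store"))
  b <- ref_bounds(ref, chrom)
  if (start < b[1] || end > b[2] || start > end) {
    stop(sprintf("range %s:%d-%d outside stored reference (%d-%d)",
                 chrom, start, end, b[1], b[2]))
  }
  off <- ref$offsets[[chrom]]
  substr(ref$seqs[[chrom]], start - off, end - off)
}

# Like ref_seq but clips the request to the stored bounds; may return "".
ref_seq_clip <- function(ref, chrom, start, end) {
  b <- ref_bounds(ref, chrom)
  start <- max(start, b[1]); end <- min(end, b[2])
  if (start > end) return("")
  ref_seq(ref, chrom, start, end)
}
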