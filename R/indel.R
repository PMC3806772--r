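#' Indel objects
#'
#' An indel is a pure insertion or pure deletion in minimal representation:
#' exactly one of `ref_allele` / `alt_allele` is non-empty. `pos` is the
#' 1-based genomic position of the first inserted or deleted base (for an
#' insertion, the inserted bases begin at `pos` in the mutant sequence, i.e.
#' the insertion sits between reference positions `pos - 1` and `pos`).
#'
#' Indels whose length is divisible by 3 ("3n indels") preserve the reading
#' frame and are the inputs the classifier is built for; all other lengths
#' cause frameshifts and are out of scope for prediction (but representable).
#'
#' @param chrom chromosome name.
#' @param pos 1-based position of the first inserted/deleted base.
#' @param ref_allele deleted bases ("" for an insertion).
#' @param alt_allele inserted bases ("" for a deletion).
#' @param normalized whether the indel has been left-normalized.
#' @return an object of class `indel` with fields `chrom`, `pos`,
#'   `ref_allele`, `alt_allele`, `kind` ("insertion"/"deletion"), `length`,
#'   `normalized`.
#' @export
indel <- function(chrom, pos, ref_allele = "", alt_allele = "",
                  normalized = FALSE) {
  ref_allele <- toupper(ref_allele)
  alt_allele <- toupper(alt_allele)
  if (nchar(ref_allele) > 0 && nchar(alt_allele) > 0) {
    stop("not a pure indel: both alleles non-empty (trim shared context first)")
  }
  if (nchar(ref_allele) == 0 && nchar(alt_allele) == 0) {
    stop("not an indel: both alleles empty")
  }
  len <- max(nchar(ref_allele), nchar(alt_allele))
  structure(list(
    chrom = as.character(chrom),
    pos = as.integer(pos),
    ref_allele = ref_allele,
    alt_allele = alt_allele,
    kind = if (nchar(alt_allele) > 0) "insertion" else "deletion",
    length = as.integer(len),
    normalized = isTRUE(normalized)
  ), class = "indel")
}

#' @export
print.indel <- function(x, ...) {
  allele <- if (x$kind == "insertion") x$alt_allele else x$ref_allele
  cat(sprintf("%s of %d bp (%s) at %s:%d%s\n", x$kind, x$length, allele,
              x$chrom, x$pos, if (x$normalized) " [normalized]" else ""))
  invisible(x)
}

#' Is the indel frame-preserving (length divisible by 3)?
#' @param x an `indel`.
#' @export
is_3n <- function(x) {
  stopifnot(inherits(x, "indel"))
  x$length %% 3L == 0L
}

# The inserted or deleted sequence, whichever is non-empty.
indel_allele <- function(x) {
  if (x$kind == "insertion") x$alt_allele else x$ref_allele
}

#' Parse one variant record into a minimal-representation indel
#'
#' Trims context shared between REF and ALT (including the conventional VCF
#' anchor base) and adjusts the position accordingly. Rejects substitutions
#' and multi-allelic records; optionally verifies REF against the reference.
#'
#' @param chrom,pos,ref,alt the four defining fields of a VCF record
#'   (`pos` 1-based, `ref`/`alt` allele strings; `alt` must be a single
#'   allele, i.e. records must be split beforehand).
#' @param reference optional `ref_store` used to verify the REF field.
#' @return an `indel`.
#' @examples
#' parse_indel_record("chr1", 100, "ACAT", "A")   # deletion of CAT at 101
#' @export
parse_indel_record <- function(chrom, pos, ref, alt, reference = NULL) {
  pos <- as.integer(pos)
  ref <- toupper(ref); alt <- toupper(alt)
  if (grepl(",", alt, fixed = TRUE)) {
    stop("multi-allelic record at ", chrom, ":", pos,
         "; split into one ALT per record first")
  }
  if (!grepl("^[ACGTN]*$", ref) || !grepl("^[ACGTN]*$", alt)) {
    stop("non-sequence allele at ", chrom, ":", pos, " (symbolic ALTs unsupported)")
  }
  if (!is.null(reference)) {
    obs <- ref_seq(reference, chrom, pos, pos + nchar(ref) - 1L)
    if (obs != ref) {
      stop(sprintf("REF mismatch at %s:%d: record has %s, reference has %s",
                   chrom, pos, ref, obs))
    }
  }
  # trim shared leading context first (the VCF anchor base; position moves),
  # then any shared trailing context
  while (nchar(ref) > 0 && nchar(alt) > 0 &&
         substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substr(ref, 2, nchar(ref))
    alt <- substr(alt, 2, nchar(alt))
    pos <- pos + 1L
  }
  while (nchar(ref) > 0 && nchar(alt) > 0 &&
         substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1, nchar(ref) - 1L)
    alt <- substr(alt, 1, nchar(alt) - 1L)
  }
  if (nchar(ref) > 0 && nchar(alt) > 0) {
    stop("not an indel at ", chrom, ":", pos,
         ": alleles differ by substitution (", ref, ">", alt, ")")
  }
  if (nchar(ref) == 0 && nchar(alt) == 0) {
    stop("not a variant at ", chrom, ":", pos, ": REF and ALT identical")
  }
  indel(chrom, pos, ref_allele = ref, alt_allele = alt)
}

#' Read indels from a VCF file
#'
#' Reads a VCF 4.x file (plain text or gzipped) and parses every record into
#' a minimal-representation [indel()]. Records that fail to parse
#' (substitutions, multi-allelic sites, reference mismatches) are collected
#' rather than aborting the run.
#'
#' @param path VCF file.
#' @param reference optional `ref_store` for REF verification.
#' @return list with `indels` (list of `indel`), `ids` (VCF ID column),
#'   and `skipped` (data.frame of record index + reason).
#' @export
read_indel_vcf <- function(path, reference = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  indels <- list(); ids <- character(); skipped <- list()
  for (i in seq_len(nrow(fix))) {
    res <- tryCatch(
      parse_indel_record(fix[i, "CHROM"], as.integer(fix[i, "POS"]),
                         fix[i, "REF"], fix[i, "ALT"], reference = reference),
      error = function(e) e)
    if (inherits(res, "error")) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        record = i, reason = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      indels[[length(indels) + 1L]] <- res
      id <- unname(fix[i, "ID"])
      ids <- c(ids, if (is.na(id)) paste0("record", i) else id)
    }
  }
  list(indels = indels, ids = ids,
       skipped = if (length(skipped)) do.call(rbind, skipped)
                 else data.frame(record = integer(), reason = character()))
}

#' Apply an indel to a chromosome sequence
#'
#' Builds the mutant chromosome string. Used for sequence-equivalence checks
#' and by the consequence caller's oracle-style tests.
#'
#' @param sequence chromosome sequence as a character string whose first base
#'   is genomic position `offset + 1`.
#' @param x an `indel` on that chromosome.
#' @param offset 0-based offset of `sequence` (default 0).
#' @export
apply_indel <- function(sequence, x, offset = 0L) {
  stopifnot(inherits(x, "indel"))
  p <- x$pos - offset
  if (x$kind == "insertion") {
    if (p < 1L || p > nchar(sequence) + 1L) stop("insertion point outside sequence")
    paste0(substr(sequence, 1, p - 1L), x$alt_allele,
           substr(sequence, p, nchar(sequence)))
  } else {
    if (p < 1L || p + x$length - 1L > nchar(sequence)) stop("deletion outside sequence")
    if (toupper(substr(sequence, p, p + x$length - 1L)) != x$ref_allele) {
      stop("deleted allele does not match sequence at position ", x$pos)
    }
    paste0(substr(sequence, 1, p - 1L),
           substr(sequence, p + x$length, nchar(sequence)))
  }
}
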