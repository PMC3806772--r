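#' Transcript models
#'
#' A minimal gene model: ordered exons plus CDS bounds on one chromosome and
#' strand. The CDS length must be divisible by 3; transcripts violating this
#' are rejected as invalid/incomplete, mirroring standard dataset filtering
#' for coding-indel analysis.
#'
#' @param transcript_id identifier (also used as the protein id for
#'   protein-coordinate annotation tracks).
#' @param chrom chromosome name.
#' @param strand "+" or "-".
#' @param exons data.frame with `start`, `end` (1-based inclusive genomic),
#'   non-overlapping.
#' @param cds_start,cds_end genomic CDS bounds (1-based inclusive,
#'   `cds_start <= cds_end` regardless of strand).
#' @return object of class `transcript_model`; `protein_length` is the CDS
#'   codon count (including a terminal stop codon if the model carries one).
#' @export
transcript_model <- function(transcript_id, chrom, strand, exons,
                             cds_start, cds_end) {
  stopifnot(strand %in% c("+", "-"),
            is.data.frame(exons), all(c("start", "end") %in% names(exons)))
  exons <- exons[order(exons$start), c("start", "end"), drop = FALSE]
  if (any(exons$end < exons$start)) stop("exon with end < start")
  if (nrow(exons) > 1 && any(exons$start[-1] <= exons$end[-nrow(exons)])) {
    stop("overlapping exons in transcript ", transcript_id)
  }
  blocks <- cds_blocks_genomic(exons, cds_start, cds_end)
  if (!nrow(blocks)) stop("CDS does not intersect any exon in ", transcript_id)
  cds_len <- sum(blocks$end - blocks$start + 1L)
  if (cds_len %% 3L != 0L) {
    stop("invalid/incomplete transcript ", transcript_id,
         ": CDS length ", cds_len, " not divisible by 3")
  }
  structure(list(transcript_id = as.character(transcript_id),
                 chrom = as.character(chrom), strand = strand,
                 exons = exons, cds_start = as.integer(cds_start),
                 cds_end = as.integer(cds_end),
                 cds_length = as.integer(cds_len),
                 protein_length = as.integer(cds_len %/% 3L)),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("transcript %s (%s%s): %d exon(s), CDS %d-%d (%d bp, %d codons)\n",
              x$transcript_id, x$chrom, x$strand, nrow(x$exons),
              x$cds_start, x$cds_end, x$cds_length, x$protein_length))
  invisible(x)
}

# Genomic CDS blocks (exon portions inside [cds_start, cds_end]), ascending.
cds_blocks_genomic <- function(exons, cds_start, cds_end) {
  s <- pmax(exons$start, cds_start); e <- pmin(exons$end, cds_end)
  keep <- s <= e
  data.frame(start = s[keep], end = e[keep])
}

# Map a genomic position inside the CDS to its 1-based coordinate in CDS
# orientation (5' of the mRNA = 1). NA when outside the CDS.
genomic_to_cds <- function(tx, gpos) {
  blocks <- cds_blocks_genomic(tx$exons, tx$cds_start, tx$cds_end)
  lens <- blocks$end - blocks$start + 1L
  hit <- which(gpos >= blocks$start & gpos <= blocks$end)
  if (!length(hit)) return(NA_integer_)
  hit <- hit[1]
  before <- if (hit > 1L) sum(lens[seq_len(hit - 1L)]) else 0L
  plus_coord <- as.integer(before + (gpos - blocks$start[hit] + 1L))
  if (tx$strand == "+") plus_coord else tx$cds_length - plus_coord + 1L
}

#' Coding sequence of a transcript
#'
#' @param tx a `transcript_model`.
#' @param reference a `ref_store`.
#' @return CDS as a character string in transcription orientation
#'   (reverse-complemented for minus-strand transcripts).
#' @export
cds_sequence <- function(tx, reference) {
  blocks <- cds_blocks_genomic(tx$exons, tx$cds_start, tx$cds_end)
  parts <- mapply(function(s, e) ref_seq(reference, tx$chrom, s, e),
                  blocks$start, blocks$end)
  cds <- paste(parts, collapse = "")
  if (tx$strand == "-") revcomp(cds) else cds
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

translate_dna <- function(x) {
  if (!nchar(x)) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(x),
                                     no.init.codon = TRUE))
}

#' Protein-level consequence of a 3n indel
#'
#' Applies the indel to the transcript's CDS, translates both alleles and
#' diffs the proteins. Categories:
#' \describe{
#'   \item{frameshift}{indel length not divisible by 3 (out of scope for the
#'     3n classifier; route to a frameshift predictor).}
#'   \item{early_stop}{the mutant CDS gains a stop codon before the original
#'     terminus (e.g. an inserted TGA); also out of classifier scope.}
#'   \item{aa_insertion / aa_deletion}{amino acids inserted or deleted with
#'     all flanking residues unchanged (phase-0 style event).}
#'   \item{block_substitution}{a codon-straddling indel that changes
#'     neighbouring residues in addition to the net insertion/deletion.}
#'   \item{non_coding}{indel does not touch the CDS.}
#' }
#'
#' The reported `affected_span` is a 1-based inclusive residue interval in the
#' wild-type protein, placed leftmost (N-terminal-most) among equivalent
#' alignments — the protein-level counterpart of left-normalization. For a
#' pure insertion the span is the single residue immediately N-terminal of
#' the insertion point (`pure_insertion = TRUE`; an insertion before residue
#' 1 anchors on residue 1).
#'
#' @param x an `indel` overlapping the transcript.
#' @param tx a `transcript_model`.
#' @param reference a `ref_store`.
#' @return object of class `protein_consequence`: list with `category`,
#'   `affected_span` (integer length-2 or NULL), `inserted_residues`,
#'   `deleted_residues`, `pure_insertion`, `transcript_id`.
#' @export
classify_coding_consequence <- function(x, tx, reference) {
  stopifnot(inherits(x, "indel"), inherits(tx, "transcript_model"))
  if (x$chrom != tx$chrom) return(consequence("non_coding", tx))

  if (x$kind == "deletion") {
    span <- c(x$pos, x$pos + x$length - 1L)
    cpos <- vapply(span, function(p) genomic_to_cds(tx, p), integer(1))
    if (all(is.na(cpos))) return(consequence("non_coding", tx))
    if (any(is.na(cpos))) {
      stop("indel at ", x$chrom, ":", x$pos,
           " spans a CDS boundary; not supported")
    }
    cds_lo <- min(cpos); cds_hi <- max(cpos)
    # a deletion through an intron would map to non-adjacent CDS coordinates
    if (cds_hi - cds_lo + 1L != x$length) {
      stop("indel at ", x$chrom, ":", x$pos,
           " spans a CDS boundary; not supported")
    }
  } else {
    # insertion between pos-1 and pos: inside the CDS when both neighbours are
    c_at <- genomic_to_cds(tx, x$pos)
    c_before <- genomic_to_cds(tx, x$pos - 1L)
    if (is.na(c_at) || is.na(c_before)) return(consequence("non_coding", tx))
    if (abs(c_at - c_before) != 1L) {
      stop("insertion at ", x$chrom, ":", x$pos, " falls between CDS blocks")
    }
  }

  if (!is_3n(x)) return(consequence("frameshift", tx))

  wt_cds <- cds_sequence(tx, reference)
  if (x$kind == "deletion") {
    # cds_lo..cds_hi are already in CDS orientation (genomic_to_cds flips for -)
    mut_cds <- paste0(substr(wt_cds, 1, cds_lo - 1L),
                      substr(wt_cds, cds_hi + 1L, nchar(wt_cds)))
  } else {
    ins <- if (tx$strand == "-") revcomp(x$alt_allele) else x$alt_allele
    cut <- if (tx$strand == "+") genomic_to_cds(tx, x$pos - 1L)
           else genomic_to_cds(tx, x$pos)
    mut_cds <- paste0(substr(wt_cds, 1, cut), ins,
                      substr(wt_cds, cut + 1L, nchar(wt_cds)))
  }

  wt_aa <- translate_dna(wt_cds)
  mut_aa <- translate_dna(mut_cds)
  # residue count before the first stop (whole protein when no stop present)
  wt_res <- nchar(strip_stop(wt_aa))
  mut_res <- nchar(strip_stop(mut_aa))
  shift <- (nchar(mut_cds) - nchar(wt_cds)) %/% 3L
  if (!is.na(stop_index(mut_aa)) && mut_res < wt_res + shift) {
    return(consequence("early_stop", tx))
  }
  wt_prot <- strip_stop(wt_aa)
  mut_prot <- strip_stop(mut_aa)

  d <- protein_diff(wt_prot, mut_prot)
  if (nchar(d$deleted) == 0L && nchar(d$inserted) == 0L) {
    # silent at protein level cannot happen for a pure 3n indel, but guard
    return(consequence("non_coding", tx))
  }
  if (nchar(d$deleted) == 0L) {
    anchor <- max(d$prefix, 1L)
    return(consequence("aa_insertion", tx, span = c(anchor, anchor),
                       inserted = d$inserted, pure_insertion = TRUE))
  }
  span <- c(d$prefix + 1L, d$prefix + nchar(d$deleted))
  if (nchar(d$inserted) == 0L) {
    return(consequence("aa_deletion", tx, span = span, deleted = d$deleted))
  }
  consequence("block_substitution", tx, span = span,
              inserted = d$inserted, deleted = d$deleted)
}

consequence <- function(category, tx, span = NULL, inserted = "",
                        deleted = "", pure_insertion = FALSE) {
  structure(list(category = category,
                 affected_span = if (is.null(span)) NULL else as.integer(span),
                 inserted_residues = inserted, deleted_residues = deleted,
                 pure_insertion = pure_insertion,
                 transcript_id = tx$transcript_id),
            class = "protein_consequence")
}

#' @export
print.protein_consequence <- function(x, ...) {
  cat(sprintf("%s on %s", x$category, x$transcript_id))
  if (!is.null(x$affected_span)) {
    cat(sprintf(", residues %d-%d", x$affected_span[1], x$affected_span[2]))
  }
  if (nzchar(x$inserted_residues)) cat(", inserted ", x$inserted_residues)
  if (nzchar(x$deleted_residues)) cat(", deleted ", x$deleted_residues)
  cat("\n")
  invisible(x)
}

stop_index <- function(aa) {
  i <- regexpr("*", aa, fixed = TRUE)
  if (i < 0) NA_integer_ else as.integer(i)
}

strip_stop <- function(aa) {
  i <- stop_index(aa)
  if (is.na(i)) aa else substr(aa, 1, i - 1L)
}

# Leftmost-placed diff of two residue strings: maximal common suffix first,
# then the prefix is what remains shared. Returns the shared prefix length
# plus the differing segments.
protein_diff <- function(a, b) {
  na <- nchar(a); nb <- nchar(b); nmin <- min(na, nb)
  suf <- 0L
  while (suf < nmin &&
         substr(a, na - suf, na - suf) == substr(b, nb - suf, nb - suf)) {
    suf <- suf + 1L
  }
  pre <- 0L
  while (pre < nmin - suf &&
         substr(a, pre + 1L, pre + 1L) == substr(b, pre + 1L, pre + 1L)) {
    pre <- pre + 1L
  }
  list(prefix = pre,
       deleted = substr(a, pre + 1L, na - suf),
       inserted = substr(b, pre + 1L, nb - suf))
}

#' Affected residue span of a 3n indel
#'
#' The 1-based inclusive wild-type residue interval covering all inserted,
#' deleted or changed residues, as needed by the domain and disorder
#' features. Errors for early-stop and frameshift consequences, which belong
#' to the frameshift predictor, not this method.
#'
#' @inheritParams classify_coding_consequence
#' @return integer vector `c(start, end)` with attribute `pure_insertion`.
#' @export
affected_residue_span <- function(x, tx, reference) {
  cons <- classify_coding_consequence(x, tx, reference)
  if (cons$category %in% c("early_stop", "frameshift")) {
    stop("indel causes ", cons$category,
         ": out of scope for the 3n method; use a frameshift predictor")
  }
  if (cons$category == "non_coding") {
    stop("indel does not overlap the CDS of ", tx$transcript_id)
  }
  structure(cons$affected_span, pure_insertion = cons$pure_insertion)
}

#' Read transcript models from a GTF/GFF file
#'
#' Uses exon and CDS features grouped by a transcript attribute. Transcripts
#' whose CDS length is not divisible by 3 are dropped as invalid/incomplete
#' and reported in the `rejected` attribute.
#'
#' @param path GTF or GFF3 file.
#' @param format passed to `rtracklayer::import` (default "gtf").
#' @param tx_attr metadata column holding the transcript id.
#' @return named list of `transcript_model`s, with attribute `rejected`
#'   (character vector of dropped transcript ids).
#' @export
read_transcripts <- function(path, format = "gtf", tx_attr = "transcript_id") {
  gr <- rtracklayer::import(path, format = format)
  md <- S4Vectors::mcols(gr)
  if (!tx_attr %in% names(md)) {
    stop("attribute '", tx_attr, "' not found in ", path)
  }
  type <- as.character(md$type)
  txid <- as.character(md[[tx_attr]])
  keep <- type %in% c("exon", "CDS") & !is.na(txid)
  gr <- gr[keep]; type <- type[keep]; txid <- txid[keep]
  out <- list(); rejected <- character(0)
  for (id in unique(txid)) {
    sel <- txid == id
    ex <- gr[sel & type == "exon"]
    cds <- gr[sel & type == "CDS"]
    if (!length(cds)) { rejected <- c(rejected, id); next }
    if (!length(ex)) ex <- cds
    m <- tryCatch(
      transcript_model(
        id, as.character(GenomicRanges::seqnames(ex))[1],
        as.character(GenomicRanges::strand(ex))[1],
        data.frame(start = GenomicRanges::start(ex), end = GenomicRanges::end(ex)),
        min(GenomicRanges::start(cds)), max(GenomicRanges::end(cds))),
      error = function(e) e)
    if (inherits(m, "error")) rejected <- c(rejected, id) else out[[id]] <- m
  }
  attr(out, "rejected") <- rejected
  out
}

#' Pick the transcript for an indel
#'
#' When several transcripts contain the indel, takes the one with the longest
#' CDS (flagged via the `multi_hit` attribute); an explicit `transcript`
#' overrides.
#'
#' @param x an `indel`.
#' @param transcripts named list of `transcript_model`s.
#' @param transcript optional transcript id to force.
#' @return a `transcript_model` or NULL when none contains the indel.
#' @export
pick_transcript <- function(x, transcripts, transcript = NULL) {
  if (!is.null(transcript)) {
    if (!transcript %in% names(transcripts)) {
      stop("transcript not found: ", transcript)
    }
    return(transcripts[[transcript]])
  }
  hits <- Filter(function(tx) {
    tx$chrom == x$chrom && x$pos >= min(tx$exons$start) &&
      x$pos <= max(tx$exons$end)
  }, transcripts)
  if (!length(hits)) return(NULL)
  lens <- vapply(hits, `[[`, integer(1), "cds_length")
  best <- hits[[which.max(lens)]]
  attr(best, "multi_hit") <- length(hits) > 1L
  best
}

#' Write consequence calls as TSV
#'
#' @param rows data.frame with columns chrom, pos, ref, alt, transcript_id,
#'   category, affected_span, inserted_residues, deleted_residues.
#' @param path output file.
#' @export
write_consequences <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Thin a dataset to one indel per gene
#'
#' Keeps the first indel in genomic order within each gene/transcript, the
#' usual guard against over-representing genes with many catalogued indels.
#'
#' @param indels list of `indel`s.
#' @param gene_ids character vector parallel to `indels`.
#' @return integer indices of the retained indels.
#' @export
one_indel_per_gene <- function(indels, gene_ids) {
  stopifnot(length(indels) == length(gene_ids))
  pos <- vapply(indels, `[[`, integer(1), "pos")
  ord <- order(gene_ids, pos)
  keep <- ord[!duplicated(gene_ids[ord])]
  sort(keep)
}
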