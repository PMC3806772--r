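# Independent oracles and tiny fixture builders shared across tests.
# Oracles deliberately use different machinery from the implementation
# (regular expressions, hand-coded codon table, O(n^2) scans).

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# --- repeat detector oracle -------------------------------------------------
# Dumbest possible enumeration: every substring of the allele as a candidate
# unit, every start position as a candidate run, copies counted by direct
# substring comparison, maximality checked by looking one period left.
# Thresholds and winner selection as specified (max total length, ties to
# the smallest period).
oracle_find_repeat <- function(indel_seq, left_flank = "", right_flank = "") {
  s <- toupper(paste0(left_flank, indel_seq, right_flank))
  n <- nchar(s)
  a0 <- nchar(left_flank) + 1L
  a1 <- nchar(left_flank) + nchar(indel_seq)
  allele <- toupper(indel_seq)
  units <- unique(unlist(lapply(seq_len(nchar(allele)), function(p)
    substring(allele, seq_len(nchar(allele) - p + 1L),
              seq_len(nchar(allele) - p + 1L) + p - 1L))))
  best <- NULL
  for (u in units) {
    p <- nchar(u)
    for (a in seq_len(n)) {
      if (a - p >= 1L && substr(s, a - p, a - p + p - 1L) == u) next  # not maximal
      k <- 0L
      while (a + (k + 1L) * p - 1L <= n &&
             substr(s, a + k * p, a + (k + 1L) * p - 1L) == u) k <- k + 1L
      if (k == 0L) next
      st <- a; en <- a + k * p - 1L
      if (en < a0 || st > a1) next
      if (k < 2L || k * p < max(4L, 2L * p)) next
      cand <- list(unit = u, period = p, copies = k, total_length = k * p)
      if (is.null(best) || cand$total_length > best$total_length ||
          (cand$total_length == best$total_length &&
           cand$period < best$period)) best <- cand
    }
  }
  if (is.null(best)) list(is_repeat = FALSE, copies = 0L, total_length = 0L,
                          period = 0L, unit = NA_character_)
  else c(list(is_repeat = TRUE), best)
}

# --- translation oracle -----------------------------------------------------
codon_table <- local({
  bases <- c("T", "C", "A", "G")
  codons <- paste0(rep(bases, each = 16),
                   rep(rep(bases, each = 4), 4),
                   rep(bases, 16))
  # standard nuclear code, TCAG order
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",  # TTT..TGG
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  stats::setNames(aas, codons)
})

oracle_translate <- function(dna) {
  dna <- toupper(dna)
  n <- nchar(dna) %/% 3L
  paste(codon_table[substring(dna, 3 * seq_len(n) - 2, 3 * seq_len(n))],
        collapse = "")
}

# --- ROC oracle -------------------------------------------------------------
oracle_auc <- function(scores, labels, positive = "damaging") {
  pos <- which(labels == positive); neg <- which(labels != positive)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  tot / (length(pos) * length(neg))
}

# --- interval query oracle --------------------------------------------------
oracle_fraction_domains <- function(span, protein_id, df) {
  rows <- df[df$seq == protein_id, , drop = FALSE]
  if (!nrow(rows)) return(0)
  hits <- 0
  for (r in seq_len(nrow(rows))) {
    if (any(seq(rows$start[r], rows$end[r]) %in% seq(span[1], span[2]))) {
      hits <- hits + 1
    }
  }
  hits / nrow(rows)
}

oracle_in_disorder <- function(span, protein_id, df) {
  rows <- df[df$seq == protein_id, , drop = FALSE]
  residues <- seq(span[1], span[2])
  inside <- vapply(residues, function(r) {
    nrow(rows) > 0 && any(rows$start <= r & rows$end >= r)
  }, logical(1))
  mean(inside) > 0.5
}

# --- small genomic fixtures -------------------------------------------------
# a one-gene reference whose CDS is the given codon string
toy_gene <- function(codons, chrom = "c1", pad = 20L) {
  cds <- paste(codons, collapse = "")
  seq <- paste0(random_dna(pad), cds, random_dna(pad))
  ref <- ref_store(stats::setNames(seq, chrom))
  tx <- transcript_model("TX1", chrom, "+",
                         data.frame(start = pad + 1L,
                                    end = pad + nchar(cds)),
                         pad + 1L, pad + nchar(cds))
  list(ref = ref, tx = tx, cds_start = pad + 1L, seq = seq)
}

# random non-stop codons
sample_codons <- function(n) {
  pool <- indeltree:::codon_pool()
  sample(pool, n, replace = TRUE)
}

# an in-memory annotation bundle over explicit tables
toy_tracks <- function(ref, domains = NULL, disorder = NULL, cons = NULL) {
  empty <- data.frame(seq = character(), start = integer(), end = integer())
  list(reference = ref,
       domains = interval_track(domains %||% empty, "protein"),
       disorder = interval_track(disorder %||% empty, "protein"),
       conservation = score_track(
         cons %||% data.frame(seq = character(), start = integer(),
                              end = integer(), score = numeric())))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
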