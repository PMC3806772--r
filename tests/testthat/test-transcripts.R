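test_that("transcript models validate exon structure and CDS length", {
  ex <- data.frame(start = 11, end = 40)
  tx <- transcript_model("T1", "c1", "+", ex, 11, 40)
  expect_equal(tx$cds_length, 30L)
  expect_equal(tx$protein_length, 10L)
  # CDS not divisible by 3 -> invalid/incomplete
  expect_error(transcript_model("T2", "c1", "+", ex, 11, 39),
               "invalid/incomplete")
  expect_error(transcript_model("T3", "c1", "+",
                                data.frame(start = c(1, 5), end = c(10, 20)),
                                1, 20),
               "overlapping")
})

test_that("codon deletions, codon duplications and stop gains are classified", {
  # LysLys -> Lys: deletion of one AAG from (AAG)2
  g <- toy_gene(c("ATG", "AAG", "AAG", "TGC", "TAA"))
  d <- indel("c1", g$cds_start + 6L, ref_allele = "AAG")
  cons <- classify_coding_consequence(d, g$tx, g$ref)
  expect_equal(cons$category, "aa_deletion")
  expect_equal(cons$deleted_residues, "K")
  expect_equal(cons$affected_span, c(2L, 2L))   # leftmost of the K pair

  # insertion of TGA at a phase-0 position introduces an early stop
  i <- indel("c1", g$cds_start + 6L, alt_allele = "TGA")
  expect_equal(classify_coding_consequence(i, g$tx, g$ref)$category,
               "early_stop")

  # 4-base deletion: frameshift
  f <- indel("c1", g$cds_start + 6L, ref_allele = "AAGT")
  expect_equal(classify_coding_consequence(f, g$tx, g$ref)$category,
               "frameshift")

  # outside the CDS
  o <- indel("c1", 3L, alt_allele = "TTT")
  expect_equal(classify_coding_consequence(o, g$tx, g$ref)$category,
               "non_coding")
})

test_that("codon-straddling 3n deletions become block substitutions", {
  g <- toy_gene(c("ATG", "GCT", "CGA", "TGC", "AAA", "TAA"))
  # delete bases 5..7 of the CDS (phase 1): one changed + one deleted residue
  d <- indel("c1", g$cds_start + 4L,
             ref_allele = ref_seq(g$ref, "c1", g$cds_start + 4L,
                                  g$cds_start + 6L))
  cons <- classify_coding_consequence(d, g$tx, g$ref)
  expect_equal(cons$category, "block_substitution")
  expect_equal(cons$affected_span, c(2L, 3L))
  expect_equal(nchar(cons$deleted_residues), 2L)
  expect_equal(nchar(cons$inserted_residues), 1L)
})

test_that("affected spans for pure insertions anchor on the left residue", {
  g <- toy_gene(c("ATG", "CCA", "GGA", "TTC", "TAA"))
  # phase-0 insertion between codons 3 and 4
  i <- indel("c1", g$cds_start + 9L, alt_allele = "CGT")
  span <- affected_residue_span(i, g$tx, g$ref)
  expect_equal(as.integer(span), c(3L, 3L))
  expect_true(attr(span, "pure_insertion"))
  # phase-0 deletion of codon 3
  d <- indel("c1", g$cds_start + 6L, ref_allele = "GGA")
  expect_equal(as.integer(affected_residue_span(d, g$tx, g$ref)), c(3L, 3L))
  # early stop / frameshift are out of method scope
  fs <- indel("c1", g$cds_start + 6L, ref_allele = "GG")
  expect_error(affected_residue_span(fs, g$tx, g$ref), "frameshift")
})

test_that("consequence calls agree with a codon-table translation oracle", {
  set.seed(31)
  n_ok <- 0
  for (i in 1:1000) {
    L <- sample(6:30, 1)
    codons <- c("ATG", sample_codons(L), "TAA")
    g <- toy_gene(codons)
    cds <- paste(codons, collapse = "")
    pos <- g$cds_start + sample(3:(nchar(cds) - 7), 1)
    x <- if (runif(1) < 0.5) {
      indel("c1", pos, alt_allele = random_dna(3))
    } else {
      indel("c1", pos, ref_allele = ref_seq(g$ref, "c1", pos, pos + 2))
    }
    got <- classify_coding_consequence(x, g$tx, g$ref)
    # oracle: edit the CDS string directly, translate by hand-coded table
    cpos <- pos - g$cds_start + 1L
    mut <- if (x$kind == "insertion") {
      paste0(substr(cds, 1, cpos - 1), x$alt_allele,
             substr(cds, cpos, nchar(cds)))
    } else {
      paste0(substr(cds, 1, cpos - 1), substr(cds, cpos + 3, nchar(cds)))
    }
    wt_aa <- oracle_translate(cds); mut_aa <- oracle_translate(mut)
    strip <- function(a) sub("\\*.*$", "", a)
    early <- grepl("\\*", mut_aa) &&
      nchar(strip(mut_aa)) < nchar(strip(wt_aa)) +
        (nchar(mut) - nchar(cds)) / 3
    if (early) {
      expect_equal(got$category, "early_stop")
      next
    }
    wt_p <- strip(wt_aa); mut_p <- strip(mut_aa)
    # recover inserted/deleted residues by leftmost alignment
    nmin <- min(nchar(wt_p), nchar(mut_p)); suf <- 0
    while (suf < nmin && substr(wt_p, nchar(wt_p) - suf, nchar(wt_p) - suf) ==
           substr(mut_p, nchar(mut_p) - suf, nchar(mut_p) - suf)) suf <- suf + 1
    pre <- 0
    while (pre < nmin - suf && substr(wt_p, pre + 1, pre + 1) ==
           substr(mut_p, pre + 1, pre + 1)) pre <- pre + 1
    del <- substr(wt_p, pre + 1, nchar(wt_p) - suf)
    ins <- substr(mut_p, pre + 1, nchar(mut_p) - suf)
    want_cat <- if (nchar(del) == 0) "aa_insertion"
                else if (nchar(ins) == 0) "aa_deletion"
                else "block_substitution"
    expect_equal(got$category, want_cat, info = paste(cds, x$kind, pos))
    expect_equal(got$deleted_residues, del)
    expect_equal(got$inserted_residues, ins)
    n_ok <- n_ok + 1
  }
  expect_gt(n_ok, 500)  # most random cases are in scope
})

test_that("minus-strand transcripts translate in CDS orientation", {
  # gene on '-': genomic sequence is the reverse complement of the CDS
  cds <- paste(c("ATG", "AAG", "AAG", "TGC", "TAA"), collapse = "")
  genomic <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  seq <- paste0(strrep("A", 10), genomic, strrep("T", 10))
  ref <- ref_store(c(c9 = seq))
  tx <- transcript_model("TM", "c9", "-",
                         data.frame(start = 11, end = 10 + nchar(cds)),
                         11, 10 + nchar(cds))
  expect_equal(cds_sequence(tx, ref), cds)
  # delete one AAG codon (genomic coordinates of the CTT triplet)
  del_start <- 10 + nchar(cds) - 8  # codon 2 of the CDS, minus strand
  d <- indel("c9", del_start, ref_allele = ref_seq(ref, "c9", del_start,
                                                   del_start + 2))
  cons <- classify_coding_consequence(d, tx, ref)
  expect_equal(cons$category, "aa_deletion")
  expect_equal(cons$deleted_residues, "K")
})

test_that("GTF round trip rebuilds transcript models and rejects broken CDS", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'c1\tx\ttranscript\t11\t40\t.\t+\t.\tgene_id "G1"; transcript_id "T1";',
    'c1\tx\texon\t11\t40\t.\t+\t.\tgene_id "G1"; transcript_id "T1";',
    'c1\tx\tCDS\t11\t40\t.\t+\t0\tgene_id "G1"; transcript_id "T1";',
    'c1\tx\ttranscript\t101\t120\t.\t+\t.\tgene_id "G2"; transcript_id "T2";',
    'c1\tx\texon\t101\t120\t.\t+\t.\tgene_id "G2"; transcript_id "T2";',
    'c1\tx\tCDS\t101\t120\t.\t+\t0\tgene_id "G2"; transcript_id "T2";'), gtf)
  txs <- read_transcripts(gtf)
  expect_named(txs, "T1")                  # T2 has a 20-bp CDS: rejected
  expect_equal(attr(txs, "rejected"), "T2")
  expect_equal(txs$T1$cds_length, 30L)
})

test_that("one-indel-per-gene thinning keeps the first by genomic order", {
  xs <- list(indel("c1", 50, alt_allele = "AAA"),
             indel("c1", 10, alt_allele = "AAA"),
             indel("c1", 30, alt_allele = "AAA"))
  keep <- one_indel_per_gene(xs, c("g1", "g1", "g2"))
  expect_equal(keep, c(2L, 3L))
})
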