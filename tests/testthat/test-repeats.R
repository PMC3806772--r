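test_that("worked repeat examples are called as published", {
  # ctcctc-CAT-catctg: (CAT)2
  r1 <- find_repeat("CAT", "ctcctc", "catctg")
  expect_true(r1$is_repeat)
  expect_equal(r1$unit, "CAT")
  expect_equal(r1$period, 3L)
  expect_equal(r1$copies, 2L)
  expect_equal(r1$total_length, 6L)

  # atcgg-CCC-ccacc: C repeated 5 times -> (C)5, mono beats larger periods
  r2 <- find_repeat("CCC", "atcgg", "ccacc")
  expect_true(r2$is_repeat)
  expect_equal(r2$unit, "C")
  expect_equal(r2$period, 1L)
  expect_equal(r2$copies, 5L)

  # no tandem copy anywhere
  r3 <- find_repeat("CAT", "ggacc", "ttgaa")
  expect_false(r3$is_repeat)
  expect_equal(r3$copies, 0L)
  expect_equal(r3$total_length, 0L)

  expect_error(find_repeat("", "aa", "bb"), "non-empty")
})

test_that("period-specific minimum lengths gate repeat calls", {
  # (C)3 spans only 3 bases: below the mononucleotide minimum of 4
  expect_false(find_repeat("C", "gt", "ccat")$is_repeat)
  # CCCC reaches it
  expect_true(find_repeat("C", "gt", "ccca")$is_repeat)
  # (CAT)2 = 6 bases meets the trinucleotide minimum; a dinucleotide pair
  # (4 bases) meets max(4, 2*2)
  expect_true(find_repeat("CA", "gg", "catt")$is_repeat)
  expect_equal(indeltree:::min_repeat_length(1), 4)
  expect_equal(indeltree:::min_repeat_length(3), 6)
  expect_equal(indeltree:::min_repeat_length(5), 10)
})

test_that("repeat detector matches the brute-force tiling oracle", {
  set.seed(42)
  for (i in 1:1000) {
    # low-cardinality alphabet pockets make repeats common
    alpha <- sample(c("A", "C", "G", "T"), sample(2:4, 1))
    mk <- function(n) paste(sample(alpha, n, replace = TRUE), collapse = "")
    allele <- mk(sample(c(1:6), 1))
    left <- mk(sample(0:25, 1))
    right <- mk(sample(0:25, 1))
    got <- find_repeat(allele, left, right)
    want <- oracle_find_repeat(allele, left, right)
    expect_equal(got$is_repeat, want$is_repeat,
                 info = paste(left, allele, right))
    expect_equal(got$copies, want$copies, info = paste(left, allele, right))
    expect_equal(got$total_length, want$total_length,
                 info = paste(left, allele, right))
    # when total length and period tie, several units describe the same
    # repeat equally well; the call geometry must still agree
    expect_equal(got$period, want$period, info = paste(left, allele, right))
  }
})

test_that("one more aligned flank copy never decreases copies or length", {
  set.seed(7)
  for (i in 1:300) {
    # repeat letters and junk letters from disjoint alphabets, so flank
    # extension by an aligned copy cannot break a run across the junk edge
    u <- paste(sample(c("A", "C"), sample(1:3, 1), replace = TRUE),
               collapse = "")
    b <- sample(0:3, 1); cc <- sample(0:3, 1)
    junk <- function(n) paste(sample(c("G", "T"), n, replace = TRUE),
                              collapse = "")
    left <- paste0(junk(5), strrep(u, b))
    right <- paste0(strrep(u, cc), junk(5))
    base <- find_repeat(u, left, right)
    ext <- find_repeat(u, paste0(junk(5), strrep(u, b + 1L)), right)
    expect_gte(ext$copies, base$copies)
    expect_gte(ext$total_length, base$total_length)
  }
})

test_that("the chr12 GCA insertion normalizes to position 132547070", {
  # positions 132547070..132547087 carry six GCA copies; base 132547069 = T
  seq <- paste0("ACGT", "T", strrep("GCA", 6), "CTGACGTT")
  ref <- ref_store(c(chr12 = seq), offsets = c(chr12 = 132547064))
  x <- parse_indel_record("chr12", 132547087, "A", "AGCA")
  nx <- left_normalize(x, ref)
  expect_equal(nx$pos, 132547070L)
  expect_equal(nx$alt_allele, "GCA")
  expect_true(nx$normalized)
})

test_that("left normalization is idempotent, equivalence-preserving, and a
           no-op outside repeats", {
  ref <- ref_store(c(c1 = "GGGTTTTACGT"))
  # insertion of G into the T run with no G upstream: unchanged
  x <- indel("c1", 6, alt_allele = "G")
  expect_equal(left_normalize(x, ref)$pos, 6L)

  # deletion inside cat[CAT]ctg shifts left by 3
  ref2 <- ref_store(c(c1 = paste0("AGGA", "CATCAT", "CTGAA")))
  d <- indel("c1", 8, ref_allele = "CAT")
  nd <- left_normalize(d, ref2)
  expect_equal(nd$pos, 5L)

  set.seed(99)
  for (i in 1:1000) {
    s <- paste(sample(c("A", "C", "T"), 60, replace = TRUE), collapse = "")
    ref <- ref_store(c(z = s))
    pos <- sample(10:40, 1)
    x <- if (runif(1) < 0.5) {
      indel("z", pos, alt_allele = random_dna(sample(1:4, 1)))
    } else {
      indel("z", pos, ref_allele = substr(s, pos, pos + sample(1:4, 1) - 1))
    }
    nx <- left_normalize(x, ref)
    # idempotence
    n2 <- left_normalize(nx, ref)
    expect_equal(n2$pos, nx$pos)
    expect_equal(indeltree:::indel_allele(n2), indeltree:::indel_allele(nx))
    # the mutant chromosome is unchanged by normalization
    expect_equal(apply_indel(s, nx), apply_indel(s, x))
  }
})

test_that("normalization finds the brute-force leftmost equivalent placement", {
  set.seed(123)
  for (i in 1:300) {
    s <- paste(sample(c("A", "C"), 40, replace = TRUE), collapse = "")
    ref <- ref_store(c(z = s))
    pos <- sample(8:30, 1)
    len <- sample(c(1, 3), 1)
    x <- if (runif(1) < 0.5) {
      indel("z", pos, alt_allele = random_dna(len))
    } else {
      indel("z", pos, ref_allele = substr(s, pos, pos + len - 1))
    }
    mut <- apply_indel(s, x)
    # brute force: smallest position whose single edit reproduces `mut`
    brute <- NA_integer_
    for (p in 1:pos) {
      if (x$kind == "insertion") {
        ins <- substr(mut, p, p + len - 1)
        cand <- paste0(substr(s, 1, p - 1), ins, substr(s, p, nchar(s)))
      } else {
        cand <- paste0(substr(s, 1, p - 1), substr(s, p + len, nchar(s)))
      }
      if (cand == mut) { brute <- p; break }
    }
    expect_equal(left_normalize(x, ref)$pos, brute)
  }
})

test_that("repeat context against a reference mirrors direct flank calls", {
  ref <- ref_store(c(c1 = paste0("AAAAA", "CTCCTC", "CAT", "CATCTG", "AAAAA")))
  # deletion of CAT at position 12 with the published flanks
  x <- indel("c1", 12, ref_allele = "CAT")
  rc <- repeat_context(x, ref, window = 6)
  expect_true(rc$is_repeat)
  expect_equal(rc$unit, "CAT")
  expect_equal(rc$copies, 2L)
})

test_that("repeat summaries tabulate totals, periods and period-3 fraction", {
  calls <- list(
    find_repeat("CAT", "ctcctc", "catctg"),   # (3,2)
    find_repeat("CAT", "ctcctc", "catctg"),   # (3,2)
    find_repeat("CCC", "atcgg", "ccacc"))     # (1,5)
  dist <- repeat_length_distribution(calls)
  expect_equal(dist$by_total_length$count[dist$by_total_length$total_length == 6], 2)
  expect_equal(dist$by_total_length$count[dist$by_total_length$total_length == 5], 1)
  expect_equal(dist$fraction_period_div3, 2 / 3)
  expect_equal(dist$n_repeat, 3)
  expect_error(repeat_length_distribution(list()), "no repeat calls")
  nr <- find_repeat("CAT", "ggacc", "ttgaa")
  expect_error(repeat_length_distribution(list(nr)), "no repeat-positive")
})
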