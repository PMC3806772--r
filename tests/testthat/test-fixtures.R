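# one modest bundle shared by the tests in this file
fx_dir <- file.path(tempdir(), "fixture_rules_small")
fx <- generate_fixture(
  fixture_spec(n_damaging = 60, n_neutral = 60, n_genes = 8, mode = "rules",
               label_noise = 0, n_frameshift = 3, n_early_stop = 2,
               seed = 501),
  fx_dir)

test_that("fixture bundles are complete and internally consistent", {
  for (f in fx$files) expect_true(file.exists(f))
  manifest <- jsonlite::read_json(fx$files$manifest)
  expect_equal(manifest$n_indels, 120)
  # recorded hashes match the files on disk
  for (entry in manifest$files) {
    expect_equal(unname(tools::md5sum(file.path(fx_dir, entry$path))),
                 entry$md5, info = entry$path)
  }
})

test_that("identical spec and seed regenerate a byte-identical bundle", {
  dir2 <- file.path(tempdir(), "fixture_rules_twin")
  fx2 <- generate_fixture(
    fixture_spec(n_damaging = 60, n_neutral = 60, n_genes = 8, mode = "rules",
                 label_noise = 0, n_frameshift = 3, n_early_stop = 2,
                 seed = 501),
    dir2)
  for (nm in setdiff(names(fx$files), "manifest")) {
    expect_equal(unname(tools::md5sum(fx$files[[nm]])),
                 unname(tools::md5sum(fx2$files[[nm]])), info = nm)
  }
})

test_that("every generated record round-trips through the pipeline", {
  ref <- read_reference(fx$files$reference)
  txs <- read_transcripts(fx$files$transcripts)
  parsed <- read_indel_vcf(fx$files$vcf, reference = ref)
  expect_equal(nrow(parsed$skipped), 0)
  expect_length(parsed$indels, 125)        # 120 planted + 5 extras
  for (i in seq_along(parsed$indels)) {
    x <- parsed$indels[[i]]
    tx <- pick_transcript(x, txs)
    expect_false(is.null(tx))
    cons <- classify_coding_consequence(x, tx, ref)
    id <- parsed$ids[i]
    if (grepl("^fs", id)) {
      expect_equal(cons$category, "frameshift")
    } else if (grepl("^es", id)) {
      expect_equal(cons$category, "early_stop")
    } else {
      expect_true(cons$category %in% c("aa_insertion", "aa_deletion"))
    }
  }
})

test_that("extracted features equal the planted truth", {
  ft <- bundle_feature_table(fx_dir)
  expect_equal(nrow(ft), 120)              # extras drop out
  m <- match(ft$id, fx$truth$id)
  expect_equal(ft$in_repeat, fx$truth$in_repeat[m])
  expect_equal(ft$in_disorder, fx$truth$in_disorder[m])
  expect_equal(ft$pfam_fraction_affected > 0, fx$truth$pfam[m])
  expect_equal(ft$left_base_conservation, fx$truth$cons[m], tolerance = 1e-8)
  expect_equal(ft$kind, fx$truth$kind[m])
  # planted repeat indels: detector recall 1 at noise 0
  planted_rep <- fx$truth$id[fx$truth$in_repeat]
  expect_true(all(ft$in_repeat[ft$id %in% planted_rep]))
})

test_that("noise-free rule-zone planting is perfectly classified by the rules", {
  ft <- bundle_feature_table(fx_dir)
  preds <- classify_published_batch(
    ft[, c("pfam_fraction_affected", "in_repeat", "in_disorder",
           "left_base_conservation")])
  covered <- preds$rule_id %in% c("rule_4", "rule_5", "rule_10")
  expect_gt(mean(covered), 0.6)
  expect_equal(mean(preds$label[covered] == ft$label[covered]), 1)
})

test_that("planted class-conditional repeat rates are realised", {
  big <- generate_fixture(
    fixture_spec(n_damaging = 1000, n_neutral = 1000, n_genes = 40,
                 mode = "rules", seed = 733),
    file.path(tempdir(), "fixture_rates"))
  t <- big$truth
  rate_d <- mean(t$in_repeat[t$clean_class == "damaging"])
  rate_n <- mean(t$in_repeat[t$clean_class == "neutral"])
  expect_lt(abs(rate_d - 0.43), 0.03)
  expect_lt(abs(rate_n - 0.11), 0.03)
  # repeat landscape: single-codon duplications dominate -> mode at length 6
  ref <- read_reference(big$files$reference)
  reps <- t[t$in_repeat, ]
  calls <- lapply(seq_len(nrow(reps)), function(i) {
    x <- if (reps$kind[i] == "insertion") {
      indel("chrS", reps$pos[i], alt_allele = reps$allele[i])
    } else {
      indel("chrS", reps$pos[i], ref_allele = reps$allele[i])
    }
    repeat_context(left_normalize(x, ref), ref)
  })
  dist <- repeat_length_distribution(calls)
  tl <- dist$by_total_length
  expect_equal(tl$total_length[which.max(tl$count)], 6L)
  expect_gt(dist$fraction_period_div3, 0.9)
})

test_that("bayes accuracy is analytic in rules mode and calibratable", {
  s0 <- fixture_spec(mode = "rules", label_noise = 0)
  expect_equal(planted_bayes_accuracy(s0), 1)
  s10 <- fixture_spec(mode = "rules", label_noise = 0.1)
  expect_equal(planted_bayes_accuracy(s10), 0.9)
  cal <- calibrate_label_noise(s0, 0.82)
  expect_equal(cal$label_noise, 0.18, tolerance = 1e-12)
  expect_equal(planted_bayes_accuracy(cal), 0.82)
})

test_that("independent-mode bayes accuracy matches a Monte-Carlo argmax", {
  spec <- fixture_spec(n_damaging = 300, n_neutral = 700,
                       mode = "independent", seed = 3,
                       cons_sd = c(damaging = 0.8, neutral = 0.8))
  a <- planted_bayes_accuracy(spec)
  # Monte-Carlo oracle: simulate features, apply the exact posterior argmax
  set.seed(999)
  N <- 100000
  piD <- 0.3
  cls <- sample(c("damaging", "neutral"), N, TRUE, prob = c(piD, 1 - piD))
  pf <- runif(N) < spec$domain_rate[cls]
  rp <- runif(N) < spec$repeat_rate[cls]
  ds <- runif(N) < spec$disorder_rate[cls]
  cs <- rnorm(N, spec$cons_mean[cls], spec$cons_sd[cls])
  lik <- function(k) {
    b <- function(rate, on) ifelse(on, rate, 1 - rate)
    b(spec$domain_rate[k], pf) * b(spec$repeat_rate[k], rp) *
      b(spec$disorder_rate[k], ds) *
      dnorm(cs, spec$cons_mean[k], spec$cons_sd[k])
  }
  pred <- ifelse(piD * lik("damaging") > (1 - piD) * lik("neutral"),
                 "damaging", "neutral")
  expect_lt(abs(a - mean(pred == cls)), 0.01)
  # infeasible calibration target is refused
  weak <- fixture_spec(n_damaging = 500, n_neutral = 500,
                       mode = "independent",
                       domain_rate = c(damaging = 0.5, neutral = 0.5),
                       repeat_rate = c(damaging = 0.5, neutral = 0.5),
                       disorder_rate = c(damaging = 0.5, neutral = 0.5),
                       cons_mean = c(damaging = 1, neutral = 1),
                       cons_sd = c(damaging = 1, neutral = 1))
  expect_error(calibrate_label_noise(weak, 0.9), "below target")
})

test_that("invalid fixture specs are rejected", {
  expect_error(fixture_spec(repeat_rate = c(damaging = 1.2, neutral = 0.1)),
               "rates")
  expect_error(fixture_spec(label_noise = 0.6), "below 0.5")
  expect_error(fixture_spec(n_damaging = 0), "at least one")
  expect_error(generate_fixture(fixture_spec(n_damaging = 2, n_neutral = 2,
                                             n_genes = 20),
                                tempfile()),
               "more genes than indels")
})
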