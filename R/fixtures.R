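#' Specification of a synthetic indel fixture
#'
#' Describes a fully self-contained toy dataset: a single-chromosome genome
#' of single-exon genes, a set of phase-0 single-codon 3n indels split into
#' damaging and neutral classes, and the annotation tracks (protein domains,
#' disorder, per-base conservation) that realise planted class-conditional
#' feature distributions. The defaults emulate the real training resource
#' this method family is built on: 474 disease indels versus a ~20x larger
#' neutral pool, repeat involvement of 43% versus 11%, insertion fractions
#' 89/474 and 211/474, and conservation scores drawn from Gaussians
#' straddling the published decision threshold of 1.405.
#'
#' Two planting modes:
#' \describe{
#'   \item{rules}{class is a deterministic function of the planted features,
#'     laid out as the decision list the shipped rule file encodes: a domain
#'     hit is damaging; otherwise disorder is neutral; otherwise a repeat is
#'     damaging; otherwise the conservation threshold decides. Damaging
#'     indels split across the "domain affected" (rule-10) and "conserved"
#'     zones (default weights 0.8/0.2), with an optional third
#'     `repeat_region` zone weight for experiments that need the repeat
#'     branch of the list to carry class signal of its own; neutral indels
#'     split 317:82 between the "disordered" (rule-4) and "ordered,
#'     unconserved" (rule-5) zones. Every core feature resolves its own
#'     stratum, so all four are informative and none is redundant. Class
#'     labels are then flipped independently with probability `label_noise`,
#'     so the best achievable (Bayes) accuracy is exactly
#'     `1 - label_noise`.}
#'   \item{independent}{each feature is drawn independently given the class
#'     (`domain_rate`, `repeat_rate`, `disorder_rate`, conservation
#'     Gaussians) — a simpler layout for marginal-signal experiments.}
#' }
#'
#' In rules mode the class-conditional repeat rates are preserved overall:
#' the repeat zone is always in a repeat, the rule-5 and conserved zones
#' never are (their class would otherwise be ambiguous), and the residual
#' zones carry adjusted rates so the per-class totals match `repeat_rate`.
#'
#' @param n_damaging,n_neutral class sizes.
#' @param n_genes number of single-exon genes sharing the indels.
#' @param mode "rules" or "independent" (see above).
#' @param repeat_rate,insertion_rate named c(damaging=, neutral=) rates.
#' @param damaging_zone,neutral_zone rules-mode zone weights.
#' @param domain_rate,disorder_rate independent-mode per-class rates.
#' @param cons_mean,cons_sd per-class conservation Gaussian parameters.
#' @param cons_threshold the conservation decision threshold (1.405).
#' @param cons_margin rules-mode deadband half-width around the threshold:
#'   unconserved neutral scores are truncated at `cons_threshold -
#'   cons_margin` and conserved damaging scores at `cons_threshold +
#'   cons_margin`. A fitted split threshold always sits mid-gap between the
#'   training values on either side, so the generator leaves that gap empty,
#'   mirroring how the published 1.405 arose from a trained tree.
#' @param label_noise symmetric label-flip probability in [0, 0.5).
#' @param n_frameshift,n_early_stop extra out-of-scope records (a 2-base
#'   insertion / a TGA insertion) added to the VCF for routing tests.
#' @param seed integer; fully determines the generated bytes.
#' @return a `fixture_spec`.
#' @export
fixture_spec <- function(n_damaging = 474L, n_neutral = 9710L, n_genes = 40L,
                         mode = c("rules", "independent"),
                         repeat_rate = c(damaging = 0.43, neutral = 0.11),
                         insertion_rate = c(damaging = 89 / 474,
                                            neutral = 211 / 474),
                         damaging_zone = c(rule10 = 0.8, conserved = 0.2),
                         neutral_zone = c(rule4 = 317 / 399, rule5 = 82 / 399),
                         domain_rate = c(damaging = 0.7, neutral = 0.1),
                         disorder_rate = c(damaging = 0.2, neutral = 0.6),
                         cons_mean = c(damaging = 2.3, neutral = 0.5),
                         cons_sd = c(damaging = 0.6, neutral = 0.5),
                         cons_threshold = 1.405,
                         cons_margin = 0.2,
                         label_noise = 0,
                         n_frameshift = 0L, n_early_stop = 0L,
                         seed = 1L) {
  mode <- match.arg(mode)
  rates <- c(repeat_rate, insertion_rate, domain_rate, disorder_rate,
             label_noise)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (label_noise >= 0.5) stop("label_noise must be below 0.5")
  if (n_damaging < 1 || n_neutral < 1) stop("need at least one indel per class")
  if (n_genes < 1) stop("need at least one gene")
  structure(list(
    n_damaging = as.integer(n_damaging), n_neutral = as.integer(n_neutral),
    n_genes = as.integer(n_genes), mode = mode,
    repeat_rate = repeat_rate, insertion_rate = insertion_rate,
    damaging_zone = damaging_zone / sum(damaging_zone),
    neutral_zone = neutral_zone / sum(neutral_zone),
    domain_rate = domain_rate, disorder_rate = disorder_rate,
    cons_mean = cons_mean, cons_sd = cons_sd,
    cons_threshold = cons_threshold, cons_margin = cons_margin,
    label_noise = label_noise,
    n_frameshift = as.integer(n_frameshift),
    n_early_stop = as.integer(n_early_stop),
    seed = as.integer(seed)), class = "fixture_spec")
}

codon_pool <- function() {
  b <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all64, c("TAA", "TAG", "TGA"))
}

rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      v <- stats::rnorm(1, mean, sd)
      if (v > lower && v <= upper) { out[i] <- v; break }
    }
  }
  out
}

# draw planted per-indel feature targets; clean class per mode
plant_features <- function(spec) {
  nd <- spec$n_damaging; nn <- spec$n_neutral
  cls <- c(rep("damaging", nd), rep("neutral", nn))
  n <- nd + nn
  thr <- spec$cons_threshold
  pfam <- logical(n); dis <- logical(n); cons <- numeric(n)
  zone <- character(n)
  ins_flag <- stats::runif(n) < spec$insertion_rate[cls]
  if (spec$mode == "rules") {
    rep_flag <- logical(n)
    # residual repeat rates keep the per-class totals at repeat_rate while
    # the repeat zone is always repeated and rule-5/conserved never are
    w <- spec$damaging_zone
    w_rep <- if ("repeat_region" %in% names(w)) w[["repeat_region"]] else 0
    r10 <- (spec$repeat_rate[["damaging"]] - w_rep) / w[["rule10"]]
    if (is.na(r10) || r10 < 0 || r10 > 1) {
      stop("damaging repeat_rate incompatible with damaging_zone weights")
    }
    r4 <- spec$repeat_rate["neutral"] / spec$neutral_zone["rule4"]
    if (r4 > 1) stop("neutral repeat_rate incompatible with neutral_zone weights")
    # outside its own decision stratum, conservation is drawn from exactly
    # the rule-5 zone's distribution (neutral-side Gaussian truncated below
    # the deadband), so the score distinguishes neither class nor zone
    # anywhere the threshold rule does not fire
    bg_draw <- function() {
      rtrunc_norm(1, spec$cons_mean[["neutral"]], spec$cons_sd[["neutral"]],
                  upper = thr - spec$cons_margin)
    }
    for (i in seq_len(n)) {
      if (cls[i] == "damaging") {
        z <- sample(names(spec$damaging_zone), 1, prob = spec$damaging_zone)
        if (z == "rule10") {
          pfam[i] <- TRUE; dis[i] <- FALSE
          rep_flag[i] <- stats::runif(1) < r10
          cons[i] <- bg_draw()
        } else if (z == "repeat_region") {  # no domain, ordered, in a repeat
          pfam[i] <- FALSE; dis[i] <- FALSE; rep_flag[i] <- TRUE
          cons[i] <- bg_draw()
        } else {  # conserved zone: no domain, ordered, not repeated, conserved
          pfam[i] <- FALSE; dis[i] <- FALSE; rep_flag[i] <- FALSE
          cons[i] <- rtrunc_norm(1, spec$cons_mean["damaging"],
                                 spec$cons_sd["damaging"],
                                 lower = thr + spec$cons_margin)
        }
      } else {
        z <- sample(names(spec$neutral_zone), 1, prob = spec$neutral_zone)
        pfam[i] <- FALSE
        if (z == "rule4") {
          dis[i] <- TRUE
          rep_flag[i] <- stats::runif(1) < r4
          cons[i] <- bg_draw()
        } else {  # rule5 zone: ordered, not repeated, unconserved
          dis[i] <- FALSE; rep_flag[i] <- FALSE
          cons[i] <- rtrunc_norm(1, spec$cons_mean["neutral"],
                                 spec$cons_sd["neutral"],
                                 upper = thr - spec$cons_margin)
        }
      }
      zone[i] <- z
    }
  } else {
    rep_flag <- stats::runif(n) < spec$repeat_rate[cls]
    pfam <- stats::runif(n) < spec$domain_rate[cls]
    dis <- stats::runif(n) < spec$disorder_rate[cls]
    cons <- stats::rnorm(n, spec$cons_mean[cls], spec$cons_sd[cls])
    zone <- "independent"
  }
  flipped <- stats::runif(n) < spec$label_noise
  label <- ifelse(flipped, ifelse(cls == "damaging", "neutral", "damaging"),
                  cls)
  data.frame(id = sprintf("ind%05d", seq_len(n)), clean_class = cls,
             label = label, flipped = flipped, zone = zone,
             kind = ifelse(ins_flag, "insertion", "deletion"),
             pfam = pfam, in_repeat = rep_flag, in_disorder = dis,
             cons = round(cons, 4), stringsAsFactors = FALSE)
}

#' Best achievable accuracy of a planted fixture
#'
#' The Bayes accuracy implied by the planted class-conditional feature
#' distributions, against the observed (noise-flipped) labels. In rules
#' mode the clean class is a deterministic function of the features, so the
#' value is exactly `1 - label_noise`. In independent mode the accuracy is
#' obtained by enumerating the 8 boolean feature cells and integrating the
#' per-cell maximum of the two class posteriors over the conservation
#' Gaussians (deterministic quadrature, no simulation). Used to calibrate
#' cross-validation acceptance bands.
#'
#' @param spec a `fixture_spec`.
#' @return accuracy in [0, 1].
#' @export
planted_bayes_accuracy <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  eps <- spec$label_noise
  if (spec$mode == "rules") return((1 - eps) * 1 + eps * 0)
  piD <- spec$n_damaging / (spec$n_damaging + spec$n_neutral)
  piN <- 1 - piD
  cell_prob <- function(cls, pfam, rep_, dis) {
    p <- function(rate, on) if (on) rate else 1 - rate
    p(spec$domain_rate[cls], pfam) * p(spec$repeat_rate[cls], rep_) *
      p(spec$disorder_rate[cls], dis)
  }
  acc <- 0
  for (pfam in c(TRUE, FALSE)) for (rep_ in c(TRUE, FALSE))
    for (dis in c(TRUE, FALSE)) {
      wD <- piD * cell_prob("damaging", pfam, rep_, dis)
      wN <- piN * cell_prob("neutral", pfam, rep_, dis)
      f <- function(x) {
        pmax(wD * stats::dnorm(x, spec$cons_mean["damaging"],
                               spec$cons_sd["damaging"]),
             wN * stats::dnorm(x, spec$cons_mean["neutral"],
                               spec$cons_sd["neutral"]))
      }
      acc <- acc + stats::integrate(f, -Inf, Inf, rel.tol = 1e-9)$value
    }
  (1 - eps) * acc + eps * (1 - acc)
}

#' Set the label noise that yields a target Bayes accuracy
#'
#' @param spec a `fixture_spec`.
#' @param target desired Bayes accuracy (e.g. 0.82).
#' @return the spec with `label_noise` adjusted.
#' @export
calibrate_label_noise <- function(spec, target) {
  stopifnot(inherits(spec, "fixture_spec"), target > 0.5, target < 1)
  clean <- local({ s <- spec; s$label_noise <- 0; planted_bayes_accuracy(s) })
  if (clean < target) {
    stop(sprintf("clean Bayes accuracy %.3f already below target %.3f",
                 clean, target))
  }
  # acc(eps) = (1-eps) clean + eps (1-clean) is linear in eps
  spec$label_noise <- (clean - target) / (2 * clean - 1)
  spec
}

#' Generate a synthetic fixture bundle
#'
#' Writes a complete, mutually consistent input set to `dir`:
#' `ref.fa` (one synthetic chromosome), `genes.gtf` (single-exon gene
#' models), `domains.bed` and `disorder.bed` (protein-coordinate tracks),
#' `conservation.bedGraph` (per-base scores at every indel's normalized
#' left-flank base), `indels.vcf` (anchor-base VCF records; repeat-region
#' indels are written right-shifted so normalization is exercised),
#' `labels.tsv` (observed labels), `planted.tsv` (planted truth) and
#' `manifest.json` (spec, seed, md5 hashes). Identical spec + seed produce a
#' byte-identical bundle.
#'
#' Every planted indel is a phase-0 single-codon insertion or deletion, so
#' all records round-trip through consequence calling as `aa_insertion` /
#' `aa_deletion`. Repeat-planted indels duplicate (or collapse) an adjacent
#' identical codon, the (XYZ)2 pattern that dominates real disease indels in
#' repeats; non-repeat sites are rejection-sampled until the repeat detector
#' finds nothing.
#'
#' @param spec a `fixture_spec`.
#' @param dir output directory (created if needed).
#' @return invisibly, a list with `dir`, `files` (named paths), `truth`
#'   (planted table with genomic placements) and `spec`.
#' @export
generate_fixture <- function(spec, dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)
  pool <- codon_pool()
  truth <- plant_features(spec)
  n <- nrow(truth)
  n_extra <- spec$n_frameshift + spec$n_early_stop
  W <- 8L  # codons reserved per indel window; boundary before relative codon 5

  # distribute windows round-robin over genes
  gene_of <- ((seq_len(n + n_extra) - 1L) %% spec$n_genes) + 1L
  slot_of <- ((seq_len(n + n_extra) - 1L) %/% spec$n_genes) + 1L
  slots_per_gene <- tabulate(gene_of, nbins = spec$n_genes)
  if (any(slots_per_gene == 0L)) {
    stop("more genes than indels: reduce n_genes")
  }
  # gene g: codon 1 = ATG, then slots * W codons, then stop codon
  gene_codons <- lapply(seq_len(spec$n_genes), function(g) {
    c("ATG", sample(pool, slots_per_gene[g] * W, replace = TRUE), "TAA")
  })
  boundary_codon <- function(i) 1L + (slot_of[i] - 1L) * W + 5L

  # plant repeat / non-repeat structure codon by codon
  inserted_codon <- rep(NA_character_, n + n_extra)
  for (i in seq_len(n)) {
    g <- gene_of[i]; bc <- boundary_codon(i)
    cd <- gene_codons[[g]]
    resample_not <- function(exclude) sample(setdiff(pool, exclude), 1)
    if (truth$kind[i] == "insertion") {
      if (truth$in_repeat[i]) {
        unit <- cd[bc - 1L]
        if (cd[bc - 2L] == unit) cd[bc - 2L] <- resample_not(unit)
        if (cd[bc] == unit) cd[bc] <- resample_not(unit)
        inserted_codon[i] <- unit
      } else {
        inserted_codon[i] <- resample_not(c(cd[bc - 1L], cd[bc]))
      }
    } else {
      if (truth$in_repeat[i]) {
        cd[bc] <- cd[bc - 1L]
        if (cd[bc - 2L] == cd[bc]) cd[bc - 2L] <- resample_not(cd[bc])
        if (cd[bc + 1L] == cd[bc]) cd[bc + 1L] <- resample_not(cd[bc])
      } else {
        if (cd[bc] == cd[bc - 1L]) cd[bc] <- resample_not(c(cd[bc - 1L], cd[bc + 1L]))
        if (cd[bc] == cd[bc + 1L]) cd[bc] <- resample_not(c(cd[bc - 1L], cd[bc + 1L]))
      }
    }
    gene_codons[[g]] <- cd
  }

  # out-of-scope extras: frameshift (2-base insertion) and early stop (TGA)
  extra <- if (n_extra > 0L) data.frame(
    id = c(sprintf("fs%03d", seq_len(spec$n_frameshift)),
           sprintf("es%03d", seq_len(spec$n_early_stop))),
    what = c(rep("frameshift", spec$n_frameshift),
             rep("early_stop", spec$n_early_stop)),
    stringsAsFactors = FALSE) else NULL

  # chromosome layout: 100 bp intergenic spacers between single-exon genes;
  # codon counts are fixed, so gene coordinates never move during the
  # verification passes below
  intergenic <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                           replace = TRUE), collapse = "")
  igs <- vapply(seq_len(spec$n_genes + 1L), function(i) intergenic(100L),
                character(1))
  gene_len <- vapply(gene_codons, function(cd) 3L * length(cd), integer(1))
  gene_start <- 100L * seq_len(spec$n_genes) +
    c(0L, cumsum(gene_len))[seq_len(spec$n_genes)] + 1L
  chrom <- "chrS"
  build_chrom <- function() {
    paste0(paste0(vapply(seq_len(spec$n_genes), function(g) {
      paste0(igs[g], paste(gene_codons[[g]], collapse = ""))
    }, character(1)), collapse = ""), igs[spec$n_genes + 1L])
  }
  genomic_pos <- function(i) {
    gene_start[gene_of[i]] + 3L * (boundary_codon(i) - 1L)
  }
  make_indel <- function(i) {
    if (truth$kind[i] == "insertion") {
      indel(chrom, genomic_pos(i), alt_allele = inserted_codon[i])
    } else {
      indel(chrom, genomic_pos(i),
            ref_allele = gene_codons[[gene_of[i]]][boundary_codon(i)])
    }
  }

  # verification passes: the realised repeat context (after normalization,
  # exactly as extraction sees it) must match the plan; accidental repeats
  # at non-repeat sites are re-rolled. Window patches cannot flip other
  # windows (a qualifying run would have to bridge >= 6 untouched codons).
  recheck <- seq_len(n)
  for (round in seq_len(25L)) {
    chrom_seq <- build_chrom()
    ref <- ref_store(stats::setNames(chrom_seq, chrom))
    bad <- integer(0)
    for (i in recheck) {
      nx <- left_normalize(make_indel(i), ref)
      rc <- repeat_context(nx, ref, window = 50L)
      if (rc$is_repeat != truth$in_repeat[i]) {
        if (truth$in_repeat[i]) {
          stop("internal: planted repeat not detected for ", truth$id[i])
        }
        bad <- c(bad, i)
      }
    }
    if (!length(bad)) break
    if (round == 25L) stop("could not realise non-repeat contexts")
    for (i in bad) {
      g <- gene_of[i]; bc <- boundary_codon(i); cd <- gene_codons[[g]]
      for (j in (bc - 2L):(bc + 2L)) cd[j] <- sample(pool, 1)
      if (truth$kind[i] == "insertion") {
        inserted_codon[i] <- sample(setdiff(pool, c(cd[bc - 1L], cd[bc])), 1)
      } else if (cd[bc] == cd[bc - 1L] || cd[bc] == cd[bc + 1L]) {
        cd[bc] <- sample(setdiff(pool, c(cd[bc - 1L], cd[bc + 1L])), 1)
      }
      gene_codons[[g]] <- cd
    }
    recheck <- bad
  }
  truth$gene <- gene_of[seq_len(n)]
  truth$transcript <- sprintf("TX%03d", truth$gene)
  truth$pos <- vapply(seq_len(n), genomic_pos, integer(1))
  truth$allele <- vapply(seq_len(n), function(i) {
    if (truth$kind[i] == "insertion") inserted_codon[i]
    else gene_codons[[gene_of[i]]][boundary_codon(i)]
  }, character(1))

  # realized placement: normalized position and affected residue span from
  # the same consequence caller the extraction pipeline uses, so the domain
  # and disorder intervals planted below cover exactly what extraction sees
  txs_int <- lapply(seq_len(spec$n_genes), function(g) {
    transcript_model(sprintf("TX%03d", g), chrom, "+",
                     data.frame(start = gene_start[g],
                                end = gene_start[g] + gene_len[g] - 1L),
                     gene_start[g], gene_start[g] + gene_len[g] - 1L)
  })
  truth$norm_pos <- NA_integer_
  truth$span_lo <- NA_integer_; truth$span_hi <- NA_integer_
  for (i in seq_len(n)) {
    nx <- left_normalize(make_indel(i), ref)
    cons <- classify_coding_consequence(nx, txs_int[[gene_of[i]]], ref)
    truth$norm_pos[i] <- nx$pos
    truth$span_lo[i] <- cons$affected_span[1]
    truth$span_hi[i] <- cons$affected_span[2]
  }

  # tracks: one interval per planted-positive indel, covering its realized
  # span with one residue of slack on each side (windows are disjoint, so
  # intervals never reach another indel's span)
  dom_rows <- truth[truth$pfam, c("transcript", "span_lo", "span_hi")]
  dis_rows <- truth[truth$in_disorder, c("transcript", "span_lo", "span_hi")]
  bed_line <- function(seqid, lo, hi) {
    sprintf("%s\t%d\t%d", seqid, pmax(lo - 2L, 0L), hi + 1L)  # 0-based h.o.
  }
  files <- list(
    reference = file.path(dir, "ref.fa"), transcripts = file.path(dir, "genes.gtf"),
    domains = file.path(dir, "domains.bed"),
    disorder = file.path(dir, "disorder.bed"),
    conservation = file.path(dir, "conservation.bedGraph"),
    vcf = file.path(dir, "indels.vcf"), labels = file.path(dir, "labels.tsv"),
    planted = file.path(dir, "planted.tsv"),
    manifest = file.path(dir, "manifest.json"))

  seqs <- Biostrings::DNAStringSet(stats::setNames(chrom_seq, chrom))
  Biostrings::writeXStringSet(seqs, files$reference, width = 70L)

  gtf <- character(0)
  for (g in seq_len(spec$n_genes)) {
    glen <- 3L * length(gene_codons[[g]])
    s <- gene_start[g]; e <- s + glen - 1L
    attrs <- sprintf('gene_id "G%03d"; transcript_id "TX%03d";', g, g)
    gtf <- c(gtf,
             sprintf("%s\tindeltree\ttranscript\t%d\t%d\t.\t+\t.\t%s", chrom, s, e, attrs),
             sprintf("%s\tindeltree\texon\t%d\t%d\t.\t+\t.\t%s", chrom, s, e, attrs),
             sprintf("%s\tindeltree\tCDS\t%d\t%d\t.\t+\t0\t%s", chrom, s, e, attrs))
  }
  writeLines(gtf, files$transcripts)

  writeLines(if (nrow(dom_rows)) bed_line(dom_rows$transcript,
                                          dom_rows$span_lo, dom_rows$span_hi)
             else character(0), files$domains)
  writeLines(if (nrow(dis_rows)) bed_line(dis_rows$transcript,
                                          dis_rows$span_lo, dis_rows$span_hi)
             else character(0), files$disorder)

  cons_pos <- truth$norm_pos - 1L
  bg <- sprintf("%s\t%d\t%d\t%.4f", chrom, cons_pos - 1L, cons_pos,
                truth$cons)
  writeLines(bg[order(cons_pos)], files$conservation)

  # VCF (anchor-base convention), position-sorted
  vcf_row <- function(id, pos, ref_a, alt_a) {
    anchor <- ref_seq(ref, chrom, pos - 1L, pos - 1L)
    sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.", chrom, pos - 1L, id,
            paste0(anchor, ref_a), paste0(anchor, alt_a))
  }
  rows <- vapply(seq_len(n), function(i) {
    if (truth$kind[i] == "insertion") {
      vcf_row(truth$id[i], truth$pos[i], "", truth$allele[i])
    } else {
      vcf_row(truth$id[i], truth$pos[i], truth$allele[i], "")
    }
  }, character(1))
  pos_all <- truth$pos
  if (n_extra > 0L) {
    for (j in seq_len(n_extra)) {
      i <- n + j
      p <- genomic_pos(i)
      alt <- if (extra$what[j] == "frameshift") "AC" else "TGA"
      rows <- c(rows, vcf_row(extra$id[j], p, "", alt))
      pos_all <- c(pos_all, p)
    }
  }
  vcf_header <- c("##fileformat=VCFv4.2",
                  sprintf("##contig=<ID=%s,length=%d>", chrom, nchar(chrom_seq)),
                  "##source=indeltree_fixture",
                  "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  writeLines(c(vcf_header, rows[order(pos_all)]), files$vcf)

  utils::write.table(
    truth[, c("id", "label", "clean_class", "kind", "transcript")],
    files$labels, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth, files$planted, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  manifest <- list(
    generator = "indeltree::generate_fixture",
    spec = unclass(spec),
    chrom = chrom, chrom_length = nchar(chrom_seq),
    n_indels = n, n_extra = n_extra,
    files = lapply(files[names(files) != "manifest"], function(f) {
      list(path = basename(f), md5 = unname(tools::md5sum(f)))
    }))
  jsonlite::write_json(manifest, files$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(dir = dir, files = files, truth = truth, spec = spec))
}

#' Extract the feature table of a fixture bundle (or equivalent file set)
#'
#' Runs the full pipeline — VCF parsing, left-normalization, consequence
#' calling, feature extraction — over a directory produced by
#' [generate_fixture()] and joins the observed labels.
#'
#' @param dir fixture directory.
#' @param registry optional `feature_registry` of extra features.
#' @param window repeat-search flank window (bases).
#' @return data.frame with `id`, `label`, `kind` and the feature columns.
#' @export
bundle_feature_table <- function(dir, registry = feature_registry(),
                                 window = 50L) {
  ref <- read_reference(file.path(dir, "ref.fa"))
  txs <- read_transcripts(file.path(dir, "genes.gtf"))
  tracks <- list(
    reference = ref,
    domains = load_interval_track(file.path(dir, "domains.bed"), "protein"),
    disorder = load_interval_track(file.path(dir, "disorder.bed"), "protein"),
    conservation = load_score_track(file.path(dir, "conservation.bedGraph")))
  labels <- utils::read.delim(file.path(dir, "labels.tsv"),
                              stringsAsFactors = FALSE)
  vcf <- read_indel_vcf(file.path(dir, "indels.vcf"), reference = ref)
  out <- vector("list", length(vcf$indels))
  keep <- logical(length(vcf$indels))
  for (i in seq_along(vcf$indels)) {
    x <- vcf$indels[[i]]
    if (!is_3n(x)) next
    tx <- pick_transcript(x, txs)
    if (is.null(tx)) next
    fv <- tryCatch(extract_features(x, tx, tracks, registry = registry,
                                    window = window),
                   error = function(e) NULL)
    if (is.null(fv)) next
    keep[i] <- TRUE
    out[[i]] <- cbind(data.frame(id = vcf$ids[i], stringsAsFactors = FALSE),
                      as.data.frame(fv))
  }
  feats <- do.call(rbind, out[keep])
  m <- match(feats$id, labels$id)
  feats$label <- labels$label[m]
  feats$kind <- labels$kind[m]
  feats[!is.na(feats$label), ]
}
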