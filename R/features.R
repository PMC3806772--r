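#' Feature registry for optional (non-core) features
#'
#' The classifier's four core features are always extracted. Further
#' features — e.g. physiochemical deltas of the inserted/deleted residues —
#' are added through a registry of named extractor functions. An extractor
#' receives a context list with fields `indel`, `tx`, `consequence`, `span`,
#' `tracks`, `repeat_call` and must return a single numeric or logical value.
#'
#' @return an empty `feature_registry`.
#' @export
feature_registry <- function() {
  structure(list(), class = "feature_registry")
}

core_feature_names <- c("pfam_fraction_affected", "in_repeat", "in_disorder",
                        "left_base_conservation")

#' Register an optional feature
#'
#' @param registry a `feature_registry`.
#' @param name unique feature name (core names are reserved).
#' @param fn extractor `function(ctx)`; see [feature_registry()].
#' @return the updated registry.
#' @export
register_feature <- function(registry, name, fn) {
  stopifnot(inherits(registry, "feature_registry"), is.function(fn))
  if (name %in% core_feature_names) {
    stop("'", name, "' is a core feature and cannot be re-registered")
  }
  if (name %in% names(registry)) {
    stop("feature already registered: ", name)
  }
  registry[[name]] <- fn
  registry
}

# Kyte-Doolittle hydropathy index
kd_hydropathy <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
                   E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
                   M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
                   Y = -1.3, V = 4.2)

#' Hydrophobicity-delta extractor (Kyte-Doolittle)
#'
#' Sum of hydropathy values of inserted residues minus deleted residues; a
#' ready-made optional feature for [register_feature()].
#'
#' @param ctx extraction context.
#' @export
feature_hydrophobicity_delta <- function(ctx) {
  kd_sum <- function(res) {
    if (!nzchar(res)) return(0)
    sum(kd_hydropathy[strsplit(res, "")[[1]]], na.rm = TRUE)
  }
  kd_sum(ctx$consequence$inserted_residues) -
    kd_sum(ctx$consequence$deleted_residues)
}

#' Extract the feature vector of one 3n indel
#'
#' Assembles the four core classifier features:
#' \describe{
#'   \item{pfam_fraction_affected}{fraction of the protein's domain instances
#'     overlapped by the affected residue span (0 when the protein has none).}
#'   \item{in_repeat}{whether the indel lies in a small exact tandem repeat
#'     ([find_repeat()] on the allele and its flanks).}
#'   \item{in_disorder}{whether the affected span is (majority) inside
#'     annotated disorder.}
#'   \item{left_base_conservation}{conservation score of the base 5' of the
#'     left-normalized allele (`NA` when unscored).}
#' }
#' plus any registry features. The indel is left-normalized first if it is
#' not already (normalization precedes all feature lookups, so every
#' representation of the same indel yields the same vector). Early-stop and
#' frameshift indels are rejected: they belong to a frameshift predictor.
#'
#' @param x an `indel` (3n).
#' @param tx a `transcript_model` containing it.
#' @param tracks list with elements `reference` (`ref_store`), `domains` and
#'   `disorder` (`interval_track`s in protein space), `conservation`
#'   (`score_track`).
#' @param registry optional `feature_registry`.
#' @param window flank window for repeat search (bases, default 50).
#' @return one-row `data.frame` of class `feature_vector`.
#' @export
extract_features <- function(x, tx, tracks, registry = feature_registry(),
                             window = 50L) {
  stopifnot(inherits(x, "indel"))
  for (need in c("reference", "domains", "disorder", "conservation")) {
    if (is.null(tracks[[need]])) {
      stop("annotation bundle is missing the '", need, "' track")
    }
  }
  if (!is_3n(x)) {
    stop("indel length ", x$length,
         " is not divisible by 3: frameshift, out of method scope")
  }
  if (!x$normalized) x <- left_normalize(x, tracks$reference)
  cons <- classify_coding_consequence(x, tx, tracks$reference)
  if (cons$category %in% c("early_stop", "frameshift")) {
    stop("indel causes ", cons$category,
         ": out of scope for the 3n method; use a frameshift predictor")
  }
  if (cons$category == "non_coding") {
    stop("indel does not overlap the CDS of ", tx$transcript_id)
  }
  span <- cons$affected_span
  rc <- repeat_context(x, tracks$reference, window = window)
  fv <- data.frame(
    pfam_fraction_affected = fraction_domains_affected(
      span, tx$transcript_id, tracks$domains),
    in_repeat = rc$is_repeat,
    in_disorder = in_disordered_region(span, tx$transcript_id, tracks$disorder),
    left_base_conservation = left_flank_conservation(x, tracks$conservation)
  )
  ctx <- list(indel = x, tx = tx, consequence = cons, span = span,
              tracks = tracks, repeat_call = rc)
  for (nm in names(registry)) {
    val <- registry[[nm]](ctx)
    if (length(val) != 1L) stop("feature '", nm, "' must return one value")
    fv[[nm]] <- val
  }
  class(fv) <- c("feature_vector", class(fv))
  fv
}

#' Write / read a feature matrix as TSV
#'
#' One row per indel; the header is the feature schema. A `label` column, if
#' present, is preserved. Logical columns round-trip as TRUE/FALSE, missing
#' values as NA.
#'
#' @param features data.frame of features (optionally with `id`, `label`).
#' @param path TSV file.
#' @export
write_feature_table <- function(features, path) {
  utils::write.table(features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
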