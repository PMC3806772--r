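#' Stratified k-fold cross-validation
#'
#' Divides the dataset into k equal-sized subsets (stratified by class, so
#' each fold mirrors the class balance), trains on k-1 and tests on the
#' held-out fold, and pools the k held-out confusions into one report. Every
#' sample is tested exactly once. If a training split ever lacks a class the
#' assignment is reshuffled (at most 10 attempts). Deterministic given
#' `seed`.
#'
#' @param features data.frame of features.
#' @param labels "damaging"/"neutral" vector.
#' @param k number of folds (default 10).
#' @param seed integer seed for the fold shuffle.
#' @param trainer `function(features, labels)` returning a model for
#'   `predict_fn`; defaults to [train_tree()] with `params`.
#' @param predict_fn `function(model, newdata)` returning a data.frame with
#'   `label` and `score`; defaults to [predict_tree()].
#' @param params [tree_params()] for the default trainer.
#' @param strata optional vector (e.g. "insertion"/"deletion") producing
#'   per-stratum sub-reports from the pooled predictions.
#' @return an `eval_report` with `auc` from the pooled held-out scores, plus
#'   `folds` (assignment), `predictions` (pooled per-sample label/score) and,
#'   when `strata` is given, `strata_reports`.
#' @export
kfold_cv <- function(features, labels, k = 10L, seed = 1L, trainer = NULL,
                     predict_fn = NULL, params = tree_params(),
                     strata = NULL) {
  n <- nrow(features)
  labels <- as.character(labels)
  stopifnot(n == length(labels), n >= k, k >= 2L)
  if (is.null(trainer)) {
    trainer <- function(X, y) train_tree(X, y, params = params)
  }
  if (is.null(predict_fn)) predict_fn <- predict_tree
  set.seed(seed)
  for (attempt in seq_len(10L)) {
    fold <- integer(n)
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))[seq_along(idx)]
    }
    ok <- all(vapply(seq_len(k), function(f) {
      length(unique(labels[fold != f])) == length(unique(labels))
    }, logical(1)))
    if (ok) break
    if (attempt == 10L) stop("could not build folds with both classes in every training split")
  }
  pred_label <- character(n); pred_score <- numeric(n)
  for (f in seq_len(k)) {
    test <- fold == f
    model <- trainer(features[!test, , drop = FALSE], labels[!test])
    p <- predict_fn(model, features[test, , drop = FALSE])
    pred_label[test] <- p$label
    pred_score[test] <- p$score
  }
  rep <- metrics(confusion_from_labels(labels, pred_label))
  rep$auc <- roc_auc(pred_score, labels)
  rep$folds <- fold
  rep$seed <- seed
  rep$predictions <- data.frame(label = pred_label, score = pred_score,
                                truth = labels, stringsAsFactors = FALSE)
  if (!is.null(strata)) {
    stopifnot(length(strata) == n)
    rep$strata_reports <- lapply(split(seq_len(n), strata), function(idx) {
      r <- metrics(confusion_from_labels(labels[idx], pred_label[idx]))
      if (length(unique(labels[idx])) == 2L) {
        r$auc <- roc_auc(pred_score[idx], labels[idx])
      }
      r
    })
  }
  rep
}

#' Balanced resampling evaluation
#'
#' The damaging and neutral pools of real data are unbalanced (about 1:20),
#' so evaluation repeatedly samples a neutral subset the same size as the
#' damaging set, runs k-fold CV on the balanced set, and reports each
#' metric's mean and standard deviation across repetitions.
#'
#' @param disease feature data.frame of the damaging class.
#' @param neutral_pool feature data.frame of the (larger) neutral pool.
#' @param reps number of resamplings (the published design uses 1000).
#' @param k CV folds.
#' @param seed integer seed.
#' @param ... passed to [kfold_cv()] (trainer, params, ...).
#' @return list with `mean`, `sd` (named numeric; `sd` is NULL when
#'   `reps == 1`) and `per_rep` (data.frame of per-repetition metrics).
#' @export
balanced_resampling <- function(disease, neutral_pool, reps = 1000L,
                                k = 10L, seed = 1L, ...) {
  nd <- nrow(disease)
  if (nrow(neutral_pool) < nd) {
    stop("neutral pool (", nrow(neutral_pool),
         ") smaller than disease set (", nd, ")")
  }
  set.seed(seed)
  rows <- vector("list", reps)
  metric_names <- c("sensitivity", "specificity", "precision", "accuracy",
                    "mcc", "auc")
  for (r in seq_len(reps)) {
    pick <- sample.int(nrow(neutral_pool), nd)
    X <- rbind(disease, neutral_pool[pick, , drop = FALSE])
    y <- c(rep("damaging", nd), rep("neutral", nd))
    rep_seed <- (seed + 7919L * r) %% .Machine$integer.max
    res <- kfold_cv(X, y, k = k, seed = rep_seed, ...)
    rows[[r]] <- as.data.frame(res[metric_names])
  }
  per_rep <- do.call(rbind, rows)
  list(mean = colMeans(per_rep),
       sd = if (reps > 1L) vapply(per_rep, stats::sd, numeric(1)) else NULL,
       per_rep = per_rep)
}

#' Greedy forward feature selection by cross-validated MCC
#'
#' Simplified best-first search: starting from the empty set, each step adds
#' the candidate feature whose addition gives the largest k-fold-CV MCC, and
#' the search stops as soon as no remaining feature strictly improves the
#' MCC. Ties go to the earlier candidate (lowest index). The per-step trace
#' supports a performance-versus-feature-count curve.
#'
#' @param features data.frame of candidate features (plus any columns not in
#'   `candidates`, which are ignored).
#' @param labels "damaging"/"neutral".
#' @param candidates feature names to search over (default: all columns).
#' @param k CV folds.
#' @param seed integer seed (one fixed fold assignment is reused throughout,
#'   so feature sets are compared on identical splits).
#' @param ... passed to [kfold_cv()].
#' @return list with `selected` (ordered character vector), `trace`
#'   (data.frame step/feature/mcc) and `candidate_mcc` (step-1 per-feature
#'   MCCs).
#' @export
greedy_feature_selection <- function(features, labels,
                                     candidates = names(features),
                                     k = 10L, seed = 1L, ...) {
  stopifnot(length(candidates) >= 1L,
            all(candidates %in% names(features)))
  selected <- character(0)
  best_mcc <- -Inf
  trace <- list()
  first_step <- NULL
  repeat {
    remaining <- setdiff(candidates, selected)
    if (!length(remaining)) break
    mccs <- vapply(remaining, function(f) {
      res <- kfold_cv(features[, c(selected, f), drop = FALSE], labels,
                      k = k, seed = seed, ...)
      if (is.na(res$mcc)) -Inf else res$mcc
    }, numeric(1))
    if (is.null(first_step)) first_step <- mccs
    j <- which.max(mccs)  # ties -> lowest index
    if (mccs[j] <= best_mcc) break
    selected <- c(selected, remaining[j])
    best_mcc <- mccs[j]
    trace[[length(trace) + 1L]] <- data.frame(
      step = length(selected), feature = remaining[j], mcc = best_mcc,
      stringsAsFactors = FALSE)
  }
  list(selected = selected,
       trace = if (length(trace)) do.call(rbind, trace)
               else data.frame(step = integer(), feature = character(),
                               mcc = numeric()),
       candidate_mcc = first_step)
}

#' Serialize an evaluation report
#'
#' @param report an `eval_report`.
#' @param path output file; `.json` writes JSON, anything else TSV.
#' @export
write_report <- function(report, path) {
  vals <- list(n = report$n, tp = report$confusion$tp, tn = report$confusion$tn,
               fp = report$confusion$fp, fn = report$confusion$fn,
               sensitivity = report$sensitivity,
               specificity = report$specificity,
               precision = report$precision, accuracy = report$accuracy,
               mcc = report$mcc, auc = report$auc,
               seed = report$seed %||% NA)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  } else {
    df <- data.frame(metric = names(vals),
                     value = vapply(vals, function(v) as.character(v %||% NA),
                                    character(1)))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
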