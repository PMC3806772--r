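#' Published classification rules
#'
#' The shipped rule file encodes the three decision paths published for the
#' 3n-indel tree (with their training support, correct counts and hence
#' confidences) plus explicit low-confidence default branches covering the
#' feature combinations whose original rules are not public:
#'
#' * rule_4: no domain affected, not in a repeat, in disorder -> neutral
#'   (confidence 0.918 = 291/317)
#' * rule_5: no domain affected, not in a repeat, ordered, left base not
#'   conserved (score <= 1.405) -> neutral (confidence 0.720 = 59/82)
#' * rule_10: domain affected, not in disorder -> damaging
#'   (confidence 0.894 = 254/284)
#' * default_*: remaining combinations -> damaging at confidence 0.5
#'   (repeat association and high conservation lean damaging; replaceable by
#'   supplying another rule file).
#'
#' Rules are applied first-match in file order. A missing conservation score
#' is treated as "not conserved" (it satisfies `<=` conditions and fails `>`
#' conditions), the conservative neutral-leaning default.
#'
#' @name published_rules
NULL

#' Path of the shipped rule file
#' @export
published_rules_path <- function() {
  system.file("extdata", "published_rules.tsv", package = "indeltree",
              mustWork = TRUE)
}

#' Load a rule file
#'
#' Plain-text TSV with columns `rule_id`, `conditions` (semicolon-joined
#' `feature op value` clauses; ops `==`, `<=`, `>`; empty = match-all),
#' `class`, `support`, `correct`. Confidence is recomputed as
#' `correct/support` (3 decimals). Non-default rules are checked pairwise
#' for mutual exclusivity (a shared feature with contradictory constraints);
#' overlap raises an error.
#'
#' @param path rule file (defaults to the shipped published rules).
#' @return data.frame of class `rule_set` with a parsed `tests` list-column.
#' @export
load_rule_file <- function(path = published_rules_path()) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("rule_id", "conditions", "class", "support", "correct")
  if (!all(need %in% names(df))) {
    stop("rule file must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(df$class %in% c("damaging", "neutral"))) {
    stop("rule class must be 'damaging' or 'neutral'")
  }
  df$confidence <- mapply(rule_confidence, df$correct, df$support)
  df$tests <- lapply(df$conditions, parse_conditions)
  check_rule_exclusivity(df)
  class(df) <- c("rule_set", class(df))
  df
}

parse_conditions <- function(s) {
  s <- trimws(s)
  if (!nzchar(s)) return(list())
  clauses <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
  lapply(clauses, function(cl) {
    m <- regmatches(cl, regexec("^(\\S+)\\s*(==|<=|>)\\s*(\\S+)$", cl))[[1]]
    if (length(m) != 4L) stop("cannot parse rule condition: '", cl, "'")
    val <- m[4]
    val <- if (val %in% c("TRUE", "FALSE")) as.logical(val) else as.numeric(val)
    list(feature = m[2], op = m[3], value = val)
  })
}

# TRUE iff the two condition lists are provably mutually exclusive: some
# feature is constrained incompatibly by both.
conditions_exclusive <- function(a, b) {
  for (ca in a) for (cb in b) {
    if (ca$feature != cb$feature) next
    if (ca$op == "==" && cb$op == "==" && !identical(ca$value, cb$value)) return(TRUE)
    if (ca$op == "==" && cb$op == ">" && is.numeric(ca$value) &&
        ca$value <= cb$value) return(TRUE)
    if (cb$op == "==" && ca$op == ">" && is.numeric(cb$value) &&
        cb$value <= ca$value) return(TRUE)
    if (ca$op == "<=" && cb$op == ">" && cb$value >= ca$value) return(TRUE)
    if (cb$op == "<=" && ca$op == ">" && ca$value >= cb$value) return(TRUE)
  }
  FALSE
}

check_rule_exclusivity <- function(rules) {
  idx <- which(!grepl("^default", rules$rule_id))
  if (length(idx) < 2) return(invisible(TRUE))
  for (i in idx) for (j in idx) {
    if (j <= i) next
    if (!conditions_exclusive(rules$tests[[i]], rules$tests[[j]])) {
      stop("published rules are not mutually exclusive: ",
           rules$rule_id[i], " overlaps ", rules$rule_id[j])
    }
  }
  invisible(TRUE)
}

#' Confidence of a classification rule
#'
#' The fraction of training samples following the rule's path whose class
#' matches the leaf, rounded to 3 decimals (e.g. 291/317 = 0.918).
#'
#' @param correct samples matching the leaf class.
#' @param support samples following the path.
#' @export
rule_confidence <- function(correct, support) {
  if (support <= 0) stop("rule with zero support is undefined")
  if (correct <= 0 || correct > support) {
    stop("correct count must satisfy 0 < correct <= support")
  }
  round(correct / support, 3)
}

# evaluate one clause against a feature vector; NA numeric values satisfy
# "<=" and fail ">" (missing conservation => not conserved)
clause_matches <- function(clause, fv) {
  if (!clause$feature %in% names(fv)) {
    stop("rule references feature absent from schema: ", clause$feature)
  }
  v <- fv[[clause$feature]]
  if (is.na(v)) {
    if (is.logical(clause$value)) return(FALSE)
    return(clause$op == "<=")
  }
  switch(clause$op,
         "==" = isTRUE(v == clause$value),
         "<=" = v <= clause$value,
         ">"  = v > clause$value)
}

#' Classify a feature vector with the published rules
#'
#' Applies the rules in file order; the first rule whose conditions all hold
#' decides the label and confidence. The prediction's ranking `score` (used
#' for ROC curves) is the leaf's damaging fraction: the confidence for a
#' damaging call, one minus the confidence for a neutral call.
#'
#' @param fv a `feature_vector` (or any one-row data.frame / named list
#'   containing the four core features).
#' @param rules a `rule_set` (defaults to the shipped published rules).
#' @return list of class `indel_prediction`: `label`, `confidence`,
#'   `rule_id`, `score`, `missing_conservation`.
#' @export
classify_published <- function(fv, rules = load_rule_file()) {
  if (is.data.frame(fv)) {
    stopifnot(nrow(fv) == 1L)
    fv <- as.list(fv)
  }
  missing_cons <- is.na(fv[["left_base_conservation"]])
  for (i in seq_len(nrow(rules))) {
    tests <- rules$tests[[i]]
    if (all(vapply(tests, clause_matches, logical(1), fv = fv))) {
      conf <- rules$confidence[i]
      label <- rules$class[i]
      return(structure(list(
        label = label, confidence = conf, rule_id = rules$rule_id[i],
        score = if (label == "damaging") conf else 1 - conf,
        missing_conservation = isTRUE(missing_cons)),
        class = "indel_prediction"))
    }
  }
  stop("no rule matched and the rule file has no default branch")
}

#' @export
print.indel_prediction <- function(x, ...) {
  cat(sprintf("%s (confidence %.3f, %s)\n", x$label, x$confidence, x$rule_id))
  invisible(x)
}

#' Classify many feature vectors with the published rules
#'
#' @param features data.frame, one row per indel.
#' @inheritParams classify_published
#' @return data.frame with `label`, `confidence`, `rule_id`, `score`.
#' @export
classify_published_batch <- function(features, rules = load_rule_file()) {
  out <- lapply(seq_len(nrow(features)), function(i) {
    p <- classify_published(features[i, , drop = FALSE], rules)
    data.frame(label = p$label, confidence = p$confidence,
               rule_id = p$rule_id, score = p$score,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
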