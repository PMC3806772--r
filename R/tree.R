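#' C4.5-style decision-tree induction
#'
#' Binary decision trees over numeric and logical features, in the J48/C4.5
#' family: splits are chosen by gain ratio (information gain divided by split
#' information), numeric thresholds are midpoints between sorted distinct
#' observed values, and pruning uses the pessimistic (confidence-bound) error
#' estimate with the binomial upper limit at the configured confidence.
#' Missing numeric values are sent down the majority branch, a documented
#' simplification of C4.5's fractional instances. Training is deterministic
#' given the parameters and input row order. Subtree raising is not
#' performed.
#'
#' @param pruning_confidence confidence level CF of the pessimistic error
#'   bound (J48 default 0.25; smaller prunes harder).
#' @param min_leaf minimum number of training instances per branch
#'   (J48 default 2).
#' @param prune whether to prune at all.
#' @return a `tree_params` list.
#' @export
tree_params <- function(pruning_confidence = 0.25, min_leaf = 2L,
                        prune = TRUE) {
  stopifnot(pruning_confidence > 0, pruning_confidence < 1, min_leaf >= 1)
  structure(list(pruning_confidence = pruning_confidence,
                 min_leaf = as.integer(min_leaf), prune = isTRUE(prune)),
            class = "tree_params")
}

#' Train a decision tree
#'
#' @param features data.frame of numeric/logical columns.
#' @param labels character/factor vector, classes "damaging" (positive) and
#'   "neutral".
#' @param params a [tree_params()].
#' @return object of class `indel_tree` (nested node list plus metadata).
#'   Training a single-class input yields a degenerate single-leaf tree with
#'   a warning.
#' @export
train_tree <- function(features, labels, params = tree_params()) {
  stopifnot(is.data.frame(features), nrow(features) == length(labels))
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("damaging", "neutral"))
  if (length(bad)) stop("unknown class label: ", bad[1])
  ok_type <- vapply(features, function(c) is.numeric(c) || is.logical(c),
                    logical(1))
  if (!all(ok_type)) {
    stop("features must be numeric or logical: ",
         paste(names(features)[!ok_type], collapse = ", "))
  }
  if (length(unique(labels)) < 2L) {
    warning("single-class training input: returning a one-leaf tree")
  }
  root <- grow_node(features, labels, params)
  if (params$prune) root <- prune_node(root, params$pruning_confidence)
  structure(list(root = root, schema = names(features),
                 n = length(labels), params = params),
            class = "indel_tree")
}

node_leaf <- function(labels) {
  nd <- sum(labels == "damaging"); n <- length(labels)
  cls <- if (nd * 2L > n) "damaging" else if (nd * 2L < n) "neutral"
         else "neutral"  # tie -> negative class
  correct <- if (cls == "damaging") nd else n - nd
  list(kind = "leaf", class = cls, support = n, correct = correct,
       n_damaging = nd)
}

grow_node <- function(X, y, params) {
  n <- length(y)
  if (n < 2L * params$min_leaf || length(unique(y)) == 1L) {
    return(node_leaf(y))
  }
  best <- best_split(X, y, params$min_leaf)
  if (is.null(best)) return(node_leaf(y))
  go_left <- split_mask(X[[best$feature]], best)
  left <- grow_node(X[go_left, , drop = FALSE], y[go_left], params)
  right <- grow_node(X[!go_left, , drop = FALSE], y[!go_left], params)
  if (left$kind == "leaf" && right$kind == "leaf" &&
      left$class == right$class) {
    return(node_leaf(y))  # vacuous split
  }
  list(kind = "split", feature = best$feature, type = best$type,
       threshold = best$threshold, na_left = best$na_left,
       n = n, n_damaging = sum(y == "damaging"), left = left, right = right)
}

# left branch: x <= threshold (numeric) or x == TRUE (logical);
# NA goes to the recorded majority branch
split_mask <- function(x, split) {
  if (split$type == "logical") {
    m <- x %in% TRUE
  } else {
    m <- !is.na(x) & x <= split$threshold
    m[is.na(x)] <- split$na_left
  }
  m
}

entropy_counts <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

# gain ratio of a binary partition given per-side damaging/total counts
gain_ratio_counts <- function(n_d, n, l_d, l_n) {
  r_d <- n_d - l_d; r_n <- n - l_n
  h <- entropy_counts(c(n_d, n - n_d))
  hl <- entropy_counts(c(l_d, l_n - l_d))
  hr <- entropy_counts(c(r_d, r_n - r_d))
  gain <- h - (l_n / n) * hl - (r_n / n) * hr
  split_info <- entropy_counts(c(l_n, r_n))
  if (split_info <= 0) return(c(gain = gain, ratio = -Inf))
  c(gain = gain, ratio = gain / split_info)
}

best_split <- function(X, y, min_leaf) {
  n <- length(y); n_d <- sum(y == "damaging")
  best <- NULL       # best positive-gain split
  fallback <- NULL   # best zero-gain split (XOR-style interactions)
  consider <- function(cand) {
    if (is.null(best) ||
        cand$ratio > best$ratio + 1e-12) best <<- cand
    # ties: keep the earlier feature / lower threshold (loop order does this)
  }
  for (j in seq_along(X)) {
    x <- X[[j]]
    if (is.logical(x)) {
      l_n <- sum(x %in% TRUE)
      if (l_n < min_leaf || n - l_n < min_leaf) next
      l_d <- sum(x %in% TRUE & y == "damaging")
      gr <- gain_ratio_counts(n_d, n, l_d, l_n)
      cand <- list(feature = names(X)[j], type = "logical",
                   threshold = NA_real_, na_left = FALSE,
                   ratio = gr[["ratio"]])
      if (gr["gain"] > 1e-12 && is.finite(gr["ratio"])) {
        consider(cand)
      } else if (gr["gain"] > -1e-12 && is.null(fallback)) {
        fallback <- cand
      }
    } else {
      obs <- !is.na(x)
      if (sum(obs) < 2L * min_leaf) next
      xo <- x[obs]; yo <- y[obs]
      ord <- order(xo)
      xs <- xo[ord]; ys <- yo[ord]
      m <- length(xs)
      cum_d <- cumsum(ys == "damaging")
      # candidate cuts after each position where the value changes
      cuts <- which(xs[-m] < xs[-1])
      n_na <- sum(!obs); na_d <- sum(!obs & y == "damaging")
      for (c0 in cuts) {
        thr <- (xs[c0] + xs[c0 + 1L]) / 2
        # majority branch for NAs: side with more observed instances
        na_left <- c0 >= m - c0
        l_n <- c0 + if (na_left) n_na else 0L
        l_d <- cum_d[c0] + if (na_left) na_d else 0L
        if (l_n < min_leaf || n - l_n < min_leaf) next
        gr <- gain_ratio_counts(n_d, n, l_d, l_n)
        if (gr["gain"] > 1e-12 && is.finite(gr["ratio"])) {
          consider(list(feature = names(X)[j], type = "numeric",
                        threshold = thr, na_left = na_left,
                        ratio = gr[["ratio"]]))
        }
      }
    }
  }
  # no split improves purity on its own: fall back to a zero-gain logical
  # split so purely interacting flags (XOR structure) remain learnable;
  # useless fallback subtrees are collapsed by the vacuous-split check and
  # by pruning
  best %||% fallback
}

# Pessimistic error count at confidence cf: N times the binomial upper
# confidence limit for E observed errors in N (Clopper-Pearson; reduces to
# N * (1 - cf^(1/N)) for E = 0, the classic C4.5 zero-error case).
pessimistic_errors <- function(E, N, cf) {
  if (N == 0L) return(0)
  if (E >= N) return(N)
  N * stats::qbeta(1 - cf, E + 1, N - E)
}

subtree_pess_errors <- function(node, cf) {
  if (node$kind == "leaf") {
    return(pessimistic_errors(node$support - node$correct, node$support, cf))
  }
  subtree_pess_errors(node$left, cf) + subtree_pess_errors(node$right, cf)
}

prune_node <- function(node, cf) {
  if (node$kind == "leaf") return(node)
  node$left <- prune_node(node$left, cf)
  node$right <- prune_node(node$right, cf)
  n <- node$n; nd <- node$n_damaging
  as_leaf_err <- pessimistic_errors(min(nd, n - nd), n, cf)
  if (as_leaf_err <= subtree_pess_errors(node, cf)) {
    cls <- if (nd * 2L > n) "damaging" else "neutral"
    return(list(kind = "leaf", class = cls, support = n,
                correct = max(nd, n - nd), n_damaging = nd))
  }
  node
}

#' Predict with a trained tree
#'
#' @param tree an `indel_tree`.
#' @param newdata data.frame with the training schema's columns.
#' @return data.frame with `label`, `confidence` (leaf majority fraction,
#'   3 decimals), `rule_id` (leaf path id as in [extract_rules()]) and
#'   `score` (leaf damaging fraction, the ROC ranking value).
#' @export
predict_tree <- function(tree, newdata) {
  stopifnot(inherits(tree, "indel_tree"))
  miss <- setdiff(tree$schema, names(newdata))
  if (length(miss)) stop("newdata lacks feature(s): ", paste(miss, collapse = ", "))
  rules <- extract_rules(tree)
  out <- lapply(seq_len(nrow(newdata)), function(i) {
    leaf <- descend(tree$root, newdata[i, , drop = FALSE], path = integer(0))
    conf <- rule_confidence(leaf$node$correct, leaf$node$support)
    score <- round(leaf$node$n_damaging / leaf$node$support, 6)
    data.frame(label = leaf$node$class, confidence = conf,
               rule_id = rules$rule_id[match(paste(leaf$path, collapse = "."),
                                             rules$path_key)],
               score = if (leaf$node$class == "damaging") conf else 1 - conf,
               damaging_fraction = score,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

descend <- function(node, row, path) {
  if (node$kind == "leaf") return(list(node = node, path = path))
  go_left <- {
    v <- row[[node$feature]]
    if (node$type == "logical") isTRUE(v)
    else if (is.na(v)) node$na_left
    else v <= node$threshold
  }
  if (go_left) descend(node$left, row, c(path, 0L))
  else descend(node$right, row, c(path, 1L))
}

#' Extract the rule list of a trained tree
#'
#' One rule per leaf, in depth-first (left/TRUE first) order. Conditions are
#' the conjunction of tests on the root-to-leaf path; supports sum to the
#' training-set size; confidence is the leaf's correct/support fraction.
#'
#' @param tree an `indel_tree`.
#' @return data.frame with `rule_id`, `conditions`, `class`, `support`,
#'   `correct`, `confidence` (and an internal `path_key`).
#' @export
extract_rules <- function(tree) {
  stopifnot(inherits(tree, "indel_tree"))
  acc <- list()
  walk <- function(node, conds, path) {
    if (node$kind == "leaf") {
      acc[[length(acc) + 1L]] <<- data.frame(
        conditions = paste(conds, collapse = "; "),
        class = node$class, support = node$support, correct = node$correct,
        confidence = rule_confidence(node$correct, node$support),
        path_key = paste(path, collapse = "."), stringsAsFactors = FALSE)
      return(invisible())
    }
    if (node$type == "logical") {
      lc <- sprintf("%s == TRUE", node$feature)
      rc <- sprintf("%s == FALSE", node$feature)
    } else {
      lc <- sprintf("%s <= %g", node$feature, node$threshold)
      rc <- sprintf("%s > %g", node$feature, node$threshold)
    }
    walk(node$left, c(conds, lc), c(path, 0L))
    walk(node$right, c(conds, rc), c(path, 1L))
  }
  walk(tree$root, character(0), integer(0))
  out <- do.call(rbind, acc)
  out$rule_id <- paste0("rule_", seq_len(nrow(out)))
  out[, c("rule_id", "conditions", "class", "support", "correct",
          "confidence", "path_key")]
}

#' @export
print.indel_tree <- function(x, ...) {
  cat(format_tree(x), sep = "\n")
  invisible(x)
}

#' Serialize / load a tree as indented text
#'
#' The format is round-trippable: thresholds are written with full precision
#' (17 significant digits) and [read_tree_text()] reconstructs an identical
#' tree.
#'
#' @param tree an `indel_tree`.
#' @param path text file.
#' @export
write_tree_text <- function(tree, path) {
  writeLines(format_tree(tree, digits = 17), path)
  invisible(path)
}

format_tree <- function(tree, digits = 6) {
  lines <- c(sprintf("indel_tree n=%d prune=%s cf=%s min_leaf=%d",
                     tree$n, tree$params$prune,
                     format(tree$params$pruning_confidence, digits = digits),
                     tree$params$min_leaf))
  fmt <- function(node, depth) {
    ind <- strrep("|   ", depth)
    if (node$kind == "leaf") {
      lines <<- c(lines, sprintf("%sleaf: %s (support=%d, correct=%d, damaging=%d)",
                                 ind, node$class, node$support, node$correct,
                                 node$n_damaging))
      return(invisible())
    }
    if (node$type == "logical") {
      tests <- c(sprintf("%s == TRUE", node$feature),
                 sprintf("%s == FALSE", node$feature))
    } else {
      thr <- format(node$threshold, digits = digits)
      tests <- c(sprintf("%s <= %s [na_left=%s]", node$feature, thr, node$na_left),
                 sprintf("%s > %s", node$feature, thr))
    }
    lines <<- c(lines, paste0(ind, tests[1]))
    fmt(node$left, depth + 1L)
    lines <<- c(lines, paste0(ind, tests[2]))
    fmt(node$right, depth + 1L)
  }
  fmt(tree$root, 0L)
  lines
}

#' @rdname write_tree_text
#' @export
read_tree_text <- function(path) {
  lines <- readLines(path)
  hdr <- regmatches(lines[1], regexec(
    "^indel_tree n=(\\d+) prune=(\\S+) cf=(\\S+) min_leaf=(\\d+)$", lines[1]))[[1]]
  if (length(hdr) != 5L) stop("not a serialized indel_tree: ", path)
  body <- lines[-1]
  depth_of <- function(s) (nchar(s) - nchar(sub("^(\\|   )*", "", s))) %/% 4L
  strip <- function(s) sub("^(\\|   )*", "", s)
  pos <- 1L
  parse_node <- function(depth) {
    line <- strip(body[pos])
    if (grepl("^leaf:", line)) {
      m <- regmatches(line, regexec(
        "^leaf: (\\S+) \\(support=(\\d+), correct=(\\d+), damaging=(\\d+)\\)$",
        line))[[1]]
      pos <<- pos + 1L
      return(list(kind = "leaf", class = m[2], support = as.integer(m[3]),
                  correct = as.integer(m[4]), n_damaging = as.integer(m[5])))
    }
    if (grepl("== TRUE$", line)) {
      feature <- sub(" == TRUE$", "", line)
      type <- "logical"; threshold <- NA_real_; na_left <- FALSE
    } else {
      m <- regmatches(line, regexec(
        "^(\\S+) <= (\\S+) \\[na_left=(\\S+)\\]$", line))[[1]]
      if (length(m) != 4L) stop("cannot parse tree line: ", line)
      feature <- m[2]; type <- "numeric"
      threshold <- as.numeric(m[3]); na_left <- as.logical(m[4])
    }
    pos <<- pos + 1L
    left <- parse_node(depth + 1L)
    pos <<- pos + 1L  # skip the right-branch test line
    right <- parse_node(depth + 1L)
    n <- leaf_total(left) + leaf_total(right)
    list(kind = "split", feature = feature, type = type,
         threshold = threshold, na_left = na_left, n = n,
         n_damaging = leaf_damaging(left) + leaf_damaging(right),
         left = left, right = right)
  }
  root <- parse_node(0L)
  schema <- unique(collect_features(root))
  structure(list(root = root, schema = schema, n = as.integer(hdr[2]),
                 params = tree_params(as.numeric(hdr[4]),
                                      as.integer(hdr[5]),
                                      as.logical(hdr[3]))),
            class = "indel_tree")
}

leaf_total <- function(node) {
  if (node$kind == "leaf") node$support else node$n
}
leaf_damaging <- function(node) {
  if (node$kind == "leaf") node$n_damaging else node$n_damaging
}
collect_features <- function(node) {
  if (node$kind == "leaf") return(character(0))
  c(node$feature, collect_features(node$left), collect_features(node$right))
}
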