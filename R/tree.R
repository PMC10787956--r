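# CART binary classifier ("fine tree": Gini impurity, up to 100 splits,
# minimum leaf size 1, midpoint thresholds) with stratified k-fold
# cross-validation and pooled confusion-matrix metrics.

#' Gini impurity
#'
#' `1 - sum(p_k^2)` over the class proportions of a count vector.
#'
#' @param counts Non-negative class counts, not all zero.
#' @return Impurity in `[0, 0.5]` for two classes.
#' @examples
#' gini(c(5, 5))
#' @export
gini <- function(counts) {
  if (any(counts < 0) || sum(counts) == 0) {
    stop("counts must be non-negative with a positive sum", call. = FALSE)
  }
  p <- counts / sum(counts)
  1 - sum(p^2)
}

# Best (feature, midpoint-threshold) split of rows `idx`; decrease is the
# unnormalised weighted impurity reduction n*g - nl*gl - nr*gr. Every
# valid candidate is eligible (impure nodes split even at zero decrease,
# which is what resolves XOR-type interactions). Ties are broken by
# lowest feature index, then lowest threshold (strict > keeps the first
# candidate found in scan order).
.best_split <- function(X, y01, idx, min_leaf) {
  n <- length(idx)
  n1 <- sum(y01[idx])
  parent <- n * gini(c(n - n1, n1))
  best <- NULL
  for (f in seq_len(ncol(X))) {
    v <- X[idx, f]
    ord <- order(v)
    vs <- v[ord]
    ys <- y01[idx][ord]
    distinct <- which(diff(vs) > 0)
    if (length(distinct) == 0) next
    cum1 <- cumsum(ys)
    for (cut in distinct) {
      nl <- cut; nr <- n - cut
      if (nl < min_leaf || nr < min_leaf) next
      l1 <- cum1[cut]; r1 <- n1 - l1
      dec <- parent - nl * gini(c(nl - l1, l1)) - nr * gini(c(nr - r1, r1))
      # mathematically tied decreases can differ at float precision when
      # computed from different partitions; treat <= 1e-9 as a tie and
      # keep the earlier candidate (lowest feature, lowest threshold)
      if (is.null(best) || dec > best$decrease + 1e-9) {
        best <- list(feature = f, threshold = (vs[cut] + vs[cut + 1]) / 2,
                     decrease = dec)
      }
    }
  }
  best
}

#' Fit a CART decision tree
#'
#' Greedy best-first growth: at each step the frontier node whose best
#' candidate split maximises the weighted Gini decrease is split, until
#' `max_splits` splits have been made or every frontier node is pure or
#' unsplittable. Impure nodes are split even when the best decrease is
#' zero (the preset's behaviour; this is what lets a depth-2 tree solve
#' XOR-type interactions that no single split improves).
#' Candidate thresholds are midpoints between consecutive distinct sorted
#' feature values; rows with `value < threshold` go left. Determinism:
#' ties are broken by lowest feature index, then lowest threshold, then
#' oldest frontier node.
#'
#' @param x Numeric feature matrix or data frame (rows = observations).
#' @param y Binary class labels (factor or coercible; first level is the
#'   negative class).
#' @param max_splits Maximum number of splits (default 100, the "fine
#'   tree" preset).
#' @param min_leaf Minimum rows per leaf (default 1).
#' @return Object of class `fine_tree` with the node table, class levels
#'   and feature names.
#' @seealso [predict.fine_tree()], [cv_evaluate()]
#' @export
fit_tree <- function(x, y, max_splits = 100L, min_leaf = 1L) {
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (!all(is.finite(X))) stop("non-finite feature values", call. = FALSE)
  y <- as.factor(y)
  stopifnot(nrow(X) == length(y), nrow(X) >= 1L, nlevels(y) <= 2L,
            max_splits >= 1L, min_leaf >= 1L)
  y01 <- as.integer(y) - 1L
  nodes <- list()
  new_node <- function(idx) {
    n1 <- sum(y01[idx])
    counts <- c(length(idx) - n1, n1)
    # pure or unsplittable nodes stay leaves (best = NULL)
    list(idx = idx, counts = counts, feature = NA_integer_,
         threshold = NA_real_, left = NA_integer_, right = NA_integer_,
         best = if (all(counts > 0) && length(idx) >= 2 * min_leaf)
           .best_split(X, y01, idx, min_leaf) else NULL)
  }
  nodes[[1]] <- new_node(seq_len(nrow(X)))
  n_splits <- 0L
  repeat {
    if (n_splits >= max_splits) break
    cand <- which(vapply(nodes, function(nd) {
      is.na(nd$feature) && !is.null(nd$best)
    }, logical(1)))
    if (length(cand) == 0) break
    decs <- vapply(cand, function(i) nodes[[i]]$best$decrease, numeric(1))
    pick <- cand[which.max(decs)] # which.max -> oldest node on ties
    nd <- nodes[[pick]]
    go_left <- X[nd$idx, nd$best$feature] < nd$best$threshold
    li <- length(nodes) + 1L
    nodes[[li]] <- new_node(nd$idx[go_left])
    ri <- length(nodes) + 1L
    nodes[[ri]] <- new_node(nd$idx[!go_left])
    nodes[[pick]]$feature <- nd$best$feature
    nodes[[pick]]$threshold <- nd$best$threshold
    nodes[[pick]]$left <- li
    nodes[[pick]]$right <- ri
    n_splits <- n_splits + 1L
  }
  node_tbl <- tibble::tibble(
    id = seq_along(nodes),
    feature = vapply(nodes, `[[`, integer(1), "feature"),
    threshold = vapply(nodes, `[[`, numeric(1), "threshold"),
    left = vapply(nodes, `[[`, integer(1), "left"),
    right = vapply(nodes, `[[`, integer(1), "right"),
    n = vapply(nodes, function(nd) length(nd$idx), integer(1)),
    n_neg = vapply(nodes, function(nd) nd$counts[1], numeric(1)),
    n_pos = vapply(nodes, function(nd) nd$counts[2], numeric(1))
  )
  # leaf prediction: majority class, ties to the first level
  node_tbl$prediction <- ifelse(node_tbl$n_pos > node_tbl$n_neg, 2L, 1L)
  structure(
    list(nodes = node_tbl, n_splits = n_splits, classes = levels(y),
         feature_names = colnames(X)),
    class = "fine_tree")
}

#' @export
print.fine_tree <- function(x, ...) {
  cat("<fine_tree> ", x$n_splits, " split(s), classes: ",
      paste(x$classes, collapse = " / "), "\n", sep = "")
  invisible(x)
}

#' Predict classes with a fitted tree
#'
#' Rows are routed by threshold comparison (`value < threshold` goes
#' left; values equal to the threshold go right).
#'
#' @param object A `fine_tree`.
#' @param newdata Feature matrix or data frame with the training columns.
#' @param ... Unused.
#' @return Factor of predicted classes.
#' @export
predict.fine_tree <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != length(object$feature_names)) {
    stop("newdata has ", ncol(X), " features; the tree was trained on ",
         length(object$feature_names), call. = FALSE)
  }
  nd <- object$nodes
  out <- integer(nrow(X))
  for (i in seq_len(nrow(X))) {
    node <- 1L
    while (!is.na(nd$feature[node])) {
      node <- if (X[i, nd$feature[node]] < nd$threshold[node])
        nd$left[node] else nd$right[node]
    }
    out[i] <- nd$prediction[node]
  }
  factor(object$classes[out], levels = object$classes)
}

#' Stratified k-fold assignments
#'
#' Shuffles each class with the seeded RNG and deals indices round-robin,
#' so per-fold class counts differ by at most one. Every class must have
#' at least `k` members.
#'
#' @param y Class labels.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return Integer vector of fold ids (1..k), one per observation.
#' @export
stratified_kfold <- function(y, k = 5L, seed = 1L) {
  y <- as.factor(y)
  folds <- integer(length(y))
  set.seed(seed)
  for (cl in levels(y)) {
    idx <- which(y == cl)
    if (length(idx) < k) {
      stop("class \"", cl, "\" has ", length(idx),
           " members; need at least k = ", k, call. = FALSE)
    }
    folds[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Classification metrics from a pooled confusion matrix
#'
#' @param tp,fp,tn,fn Confusion counts with the case group as positive.
#' @return Named numeric: `sensitivity`, `specificity`, `accuracy`, `ppv`
#'   (percent).
#' @examples
#' confusion_metrics(tp = 9, fp = 2, tn = 18, fn = 1)
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  c(sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp),
    accuracy = 100 * (tp + tn) / (tp + tn + fp + fn),
    ppv = 100 * tp / (tp + fp))
}

#' Cross-validated tree classification
#'
#' Stratified k-fold cross-validation of [fit_tree()]: each fold is
#' predicted by a tree trained on the remaining folds, the confusion
#' matrix is pooled over folds (micro-averaging) and sensitivity,
#' specificity, accuracy and positive predictive value are computed with
#' the case group as the positive class. Per-fold metrics are also kept.
#'
#' @param x Feature matrix or data frame.
#' @param y Binary labels.
#' @param k Folds (default 5).
#' @param seed Seed for the fold shuffle.
#' @param positive Positive class label (default `"bruxism"`; falls back
#'   to the second factor level if absent).
#' @param max_splits,min_leaf Tree parameters (see [fit_tree()]).
#' @return Object of class `tree_cv`: pooled `metrics`, `confusion`
#'   counts, per-fold tibble `folds`, `k` and `seed`.
#' @export
cv_evaluate <- function(x, y, k = 5L, seed = 1L, positive = "bruxism",
                        max_splits = 100L, min_leaf = 1L) {
  X <- as.matrix(x)
  y <- as.factor(y)
  if (!positive %in% levels(y)) positive <- levels(y)[nlevels(y)]
  folds <- stratified_kfold(y, k = k, seed = seed)
  tp <- fp <- tn <- fn <- 0
  fold_rows <- list()
  for (f in seq_len(k)) {
    train <- folds != f
    if (length(unique(y[train])) < 2) {
      stop("training folds must contain both classes", call. = FALSE)
    }
    fit <- fit_tree(X[train, , drop = FALSE], y[train],
                    max_splits = max_splits, min_leaf = min_leaf)
    pred <- predict(fit, X[!train, , drop = FALSE])
    truth <- y[!train]
    ftp <- sum(pred == positive & truth == positive)
    ffp <- sum(pred == positive & truth != positive)
    ftn <- sum(pred != positive & truth != positive)
    ffn <- sum(pred != positive & truth == positive)
    tp <- tp + ftp; fp <- fp + ffp; tn <- tn + ftn; fn <- fn + ffn
    fold_rows[[f]] <- tibble::tibble(
      fold = f, n = sum(!train),
      !!!as.list(confusion_metrics(ftp, ffp, ftn, ffn)))
  }
  structure(
    list(metrics = confusion_metrics(tp, fp, tn, fn),
         confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
         folds = dplyr::bind_rows(fold_rows),
         k = k, seed = seed, positive = positive,
         params = list(max_splits = max_splits, min_leaf = min_leaf)),
    class = "tree_cv")
}

#' @export
print.tree_cv <- function(x, ...) {
  cat("<tree_cv> ", x$k, "-fold, positive = ", x$positive, "\n", sep = "")
  print(round(x$metrics, 2))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.tree_cv <- function(x, ...) x$folds

#' @export
glance.tree_cv <- function(x, ...) {
  tibble::tibble(
    sensitivity = x$metrics[["sensitivity"]],
    specificity = x$metrics[["specificity"]],
    accuracy = x$metrics[["accuracy"]],
    ppv = x$metrics[["ppv"]],
    tp = x$confusion[["tp"]], fp = x$confusion[["fp"]],
    tn = x$confusion[["tn"]], fn = x$confusion[["fn"]],
    k = x$k, seed = x$seed)
}

#' @export
tidy.fine_tree <- function(x, ...) x$nodes

#' @export
glance.fine_tree <- function(x, ...) {
  leaves <- sum(is.na(x$nodes$feature))
  tibble::tibble(n_splits = x$n_splits, n_leaves = leaves,
                 n_nodes = nrow(x$nodes))
}
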