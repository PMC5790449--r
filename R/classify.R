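# Specimen classification: a compact bagged-CART random forest (no external
# classifier package is assumed) and chi-square attribute ranking.

# best gini split of one feature: returns c(decrease, threshold) or NULL
best_split_feature <- function(xf, y_int, n_class) {
  ord <- order(xf)
  xs <- xf[ord]
  n <- length(xs)
  valid <- which(xs[-n] < xs[-1])
  if (length(valid) == 0L) return(NULL)
  cum <- vapply(seq_len(n_class), function(k) cumsum(y_int[ord] == k),
                numeric(n))
  tot <- cum[n, ]
  nl <- valid
  nr <- n - nl
  sl <- rowSums(cum[valid, , drop = FALSE]^2)
  sr <- rowSums(sweep(cum[valid, , drop = FALSE], 2, tot, function(a, b) b - a)^2)
  # weighted gini = sum_side n_side * (1 - sum p^2); minimize
  imp <- (nl - sl / nl) + (nr - sr / nr)
  parent <- n - sum((tot / n)^2) * n
  j <- which.min(imp)
  dec <- parent - imp[j]
  if (dec <= 1e-12) return(NULL)
  c(dec, (xs[valid[j]] + xs[valid[j] + 1L]) / 2, valid[j])
}

grow_tree <- function(x, y_int, n_class, mtry, max_depth, min_node, depth = 0L) {
  n <- length(y_int)
  counts <- tabulate(y_int, n_class)
  if (depth >= max_depth || n < 2L * min_node || max(counts) == n) {
    return(list(leaf = TRUE, class = which.max(counts)))
  }
  feats <- sample.int(ncol(x), min(mtry, ncol(x)))
  best <- NULL; best_f <- NA_integer_
  for (f in feats) {
    s <- best_split_feature(x[, f], y_int, n_class)
    if (!is.null(s) && (is.null(best) || s[1] > best[1])) {
      best <- s; best_f <- f
    }
  }
  if (is.null(best)) return(list(leaf = TRUE, class = which.max(counts)))
  left <- x[, best_f] <= best[2]
  list(leaf = FALSE, feature = best_f, threshold = best[2],
       left = grow_tree(x[left, , drop = FALSE], y_int[left], n_class,
                        mtry, max_depth, min_node, depth + 1L),
       right = grow_tree(x[!left, , drop = FALSE], y_int[!left], n_class,
                         mtry, max_depth, min_node, depth + 1L))
}

predict_tree <- function(tree, x) {
  out <- integer(nrow(x))
  recurse <- function(node, idx) {
    if (length(idx) == 0L) return()
    if (node$leaf) { out[idx] <<- node$class; return() }
    left <- x[idx, node$feature] <= node$threshold
    recurse(node$left, idx[left])
    recurse(node$right, idx[!left])
  }
  recurse(tree, seq_len(nrow(x)))
  out
}

#' Fit a random forest
#'
#' Bagged classification trees: each tree is grown on a bootstrap sample with
#' `mtry` features drawn at random at every node and exhaustive gini splits.
#' Uses R's RNG, so results are reproducible under `set.seed()`.
#'
#' @param x numeric matrix, samples x features.
#' @param y factor of class labels.
#' @param ntree number of trees (default 500).
#' @param mtry features tried per node (default `floor(sqrt(p))`).
#' @param max_depth,min_node tree growth limits.
#' @return object of class `sn_forest`.
#' @export
rf_fit <- function(x, y, ntree = 500L, mtry = NULL,
                   max_depth = 12L, min_node = 2L) {
  y <- droplevels(as.factor(y))
  n_class <- nlevels(y)
  y_int <- as.integer(y)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  trees <- vector("list", ntree)
  n <- nrow(x)
  for (t in seq_len(ntree)) {
    boot <- sample.int(n, n, replace = TRUE)
    trees[[t]] <- grow_tree(x[boot, , drop = FALSE], y_int[boot], n_class,
                            mtry, max_depth, min_node)
  }
  structure(list(trees = trees, levels = levels(y), mtry = mtry),
            class = "sn_forest")
}

#' @rdname rf_fit
#' @param object an `sn_forest`.
#' @param newdata samples x features matrix (same feature order as training).
#' @param ... unused.
#' @return factor of predicted labels (majority vote, first-level tie-break).
#' @export
predict.sn_forest <- function(object, newdata, ...) {
  votes <- matrix(0L, nrow(newdata), length(object$levels))
  for (tree in object$trees) {
    p <- predict_tree(tree, newdata)
    votes[cbind(seq_len(nrow(newdata)), p)] <-
      votes[cbind(seq_len(nrow(newdata)), p)] + 1L
  }
  factor(object$levels[max.col(votes, ties.method = "first")],
         levels = object$levels)
}

#' Stratified cross-validated specimen classification
#'
#' Evaluates a random forest on `log10(x + 1)` normalized counts of the
#' detected feature set by stratified k-fold cross-validation.  When the
#' smallest class has fewer samples than `folds`, the fold count is reduced
#' with a warning.  Fully deterministic given `seed`.
#'
#' @param se `SummarizedExperiment` with `normcounts` and `specimen`, or a
#'   samples x features numeric matrix (then `labels` is required).
#' @param labels class labels (taken from `colData(se)$specimen` when
#'   missing).
#' @param seed RNG seed for fold assignment and forest growth.
#' @param folds cross-validation folds (default 10).
#' @param trees forest size (default 500).
#' @param detection optional [detect_features()] table restricting features.
#' @return list of class `classifier_report`: `accuracy`, `confusion` (rows =
#'   truth), `n_misclassified`, `scheme`, `seed`, `n_features`.
#' @export
train_evaluate <- function(se, labels = NULL, seed = 1L, folds = 10L,
                           trees = 500L, detection = NULL) {
  if (methods::is(se, "SummarizedExperiment")) {
    if (is.null(labels)) labels <- SummarizedExperiment::colData(se)$specimen
    x <- SummarizedExperiment::assay(se, "normcounts")
    if (is.null(detection)) detection <- detect_features(se)
    feats <- detection$feature[detection$pattern != ""]
    x <- t(log10(x[feats, , drop = FALSE] + 1))
  } else {
    x <- as.matrix(se)
  }
  y <- droplevels(as.factor(labels))
  if (nlevels(y) < 2L) stop("need >= 2 classes")
  min_class <- min(table(y))
  if (min_class < folds) {
    warning("smallest class has ", min_class, " samples; reducing folds")
    folds <- max(2L, min_class)
  }
  set.seed(seed)
  fold_of <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold_of[idx] <- rep_len(seq_len(folds), length(idx))
  }
  pred <- factor(rep(levels(y)[1], length(y)), levels = levels(y))
  for (f in seq_len(folds)) {
    test <- fold_of == f
    fit <- rf_fit(x[!test, , drop = FALSE], y[!test], ntree = trees)
    pred[test] <- predict(fit, x[test, , drop = FALSE])
  }
  confusion <- table(truth = y, predicted = pred)
  acc <- sum(diag(confusion)) / length(y)
  structure(list(accuracy = acc,
                 confusion = confusion,
                 n_misclassified = as.integer(length(y) - sum(diag(confusion))),
                 scheme = sprintf("stratified %d-fold CV, %d trees", folds, trees),
                 seed = seed,
                 n_features = ncol(x)),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("%s | accuracy %.1f%% (%d misclassified)\n",
              x$scheme, 100 * x$accuracy, x$n_misclassified))
  print(x$confusion)
  invisible(x)
}

#' Chi-square attribute merit
#'
#' Each feature is discretized into at most `bins` equal-frequency bins by
#' rank (tied values share a bin, so the statistic is invariant to strictly
#' monotone transforms), and the chi-square statistic of the bin x class
#' contingency table is reported as the feature's merit.  Constant features
#' get merit 0.
#'
#' @param se `SummarizedExperiment` with `normcounts` (log-transformed
#'   internally) or a samples x features matrix.
#' @param labels class labels (see [train_evaluate()]).
#' @param bins maximum number of equal-frequency bins.
#' @param detection optional [detect_features()] table restricting features.
#' @return `data.table`: `feature`, `merit`, `rank` (descending merit).
#' @export
chi_square_merit <- function(se, labels = NULL, bins = 10L, detection = NULL) {
  if (methods::is(se, "SummarizedExperiment")) {
    if (is.null(labels)) labels <- SummarizedExperiment::colData(se)$specimen
    x <- SummarizedExperiment::assay(se, "normcounts")
    if (is.null(detection)) detection <- detect_features(se)
    feats <- detection$feature[detection$pattern != ""]
    x <- t(log10(x[feats, , drop = FALSE] + 1))
  } else {
    x <- as.matrix(se)
  }
  y <- droplevels(as.factor(labels))
  n <- nrow(x)
  merit <- vapply(seq_len(ncol(x)), function(j) {
    r <- rank(x[, j], ties.method = "min")
    b <- floor((r - 1) * bins / n) + 1L
    tab <- table(b, y)
    if (nrow(tab) < 2L) return(0)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - e)^2 / e, na.rm = TRUE)
  }, numeric(1))
  out <- data.table(feature = colnames(x), merit = merit)
  setorder(out, -merit, feature)
  out[, rank := seq_len(.N)]
  out[]
}
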