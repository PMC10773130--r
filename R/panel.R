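#' Panel-evaluation configuration
#'
#' Defaults encode the standard evaluation protocol: a 4:1 stratified train/test
#' split, 5-fold cross-validation on the training set, and a random forest
#' on log2(TPM + 1) features.
#'
#' @param split_fraction Held-out test fraction (default 0.2).
#' @param cv_folds Cross-validation folds on the training set.
#' @param n_trees Trees in the forest.
#' @param seed Integer seed fixing split membership, fold assignment, and
#'   ensemble output.
#' @param stratified Preserve class balance in split and folds.
#' @return A list of class `panel_eval_config`.
#' @export
panel_eval_config <- function(split_fraction = 0.2, cv_folds = 5L,
                              n_trees = 500L, seed = 1L, stratified = TRUE) {
  stopifnot(split_fraction > 0, split_fraction < 1, cv_folds >= 2L)
  structure(list(split_fraction = split_fraction,
                 cv_folds = as.integer(cv_folds),
                 n_trees = as.integer(n_trees), seed = as.integer(seed),
                 stratified = isTRUE(stratified)),
            class = "panel_eval_config")
}

#' ROC curve and AUC from scores
#'
#' AUC is computed by the rank (Mann-Whitney) statistic — the probability
#' that a random positive outranks a random negative, ties counting one
#' half — which equals trapezoidal integration of the ROC step curve.
#'
#' @param scores Numeric prediction scores (higher = more positive).
#' @param labels Binary labels (logical, or 0/1, or a two-level factor whose
#'   second level is positive); both classes must be present.
#' @return List: `auc`, and `roc` (data.frame of fpr/tpr points from (0,0)
#'   to (1,1)).
#' @export
roc_curve <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  np <- sum(y == 1L); nn <- sum(y == 0L)
  r <- rank(scores)
  auc <- (sum(r[y == 1L]) - np * (np + 1) / 2) / (np * nn)
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  # step points at each distinct threshold
  cuts <- c(TRUE, diff(ss) != 0)
  tp <- cumsum(ys == 1L); fp <- cumsum(ys == 0L)
  keep <- which(c(cuts[-1L], TRUE))  # last index within each threshold group
  roc <- data.frame(fpr = c(0, fp[keep] / nn), tpr = c(0, tp[keep] / np))
  list(auc = auc, roc = roc)
}

as_binary_labels <- function(labels) {
  if (is.factor(labels)) as.integer(labels == levels(labels)[2L])
  else if (is.logical(labels)) as.integer(labels)
  else {
    if (!all(labels %in% c(0, 1))) stop("labels must be binary")
    as.integer(labels)
  }
}

stratified_split <- function(y, fraction, stratified) {
  test <- logical(length(y))
  if (stratified) {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      n_test <- max(1L, round(length(idx) * fraction))
      test[sample(idx, n_test)] <- TRUE
    }
  } else {
    test[sample(length(y), max(1L, round(length(y) * fraction)))] <- TRUE
  }
  test
}

stratified_folds <- function(y, k, stratified) {
  fold <- integer(length(y))
  if (stratified) {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    fold <- sample(rep_len(seq_len(k), length(y)))
  }
  fold
}

#' Evaluate a transcript panel's discriminative power
#'
#' Splits samples into stratified training and held-out test sets (4:1 by
#' default), estimates a cross-validated AUC on the training set (mean over
#' folds of the held-out-fold AUC), then refits the forest on the full
#' training set and reports the held-out test AUC. Features are
#' log2(TPM + 1)-transformed panel rows.
#'
#' @param em An `expression_matrix`.
#' @param panel Character vector of transcript ids, all present in `em`.
#' @param labels Binary label per sample: a named vector (names = sample
#'   ids) or a vector in column order.
#' @param cfg A [panel_eval_config()].
#' @return List of class `panel_eval_result`: auc_train_cv, auc_test, roc
#'   (test-set points), scores (per-test-sample predicted probabilities),
#'   test_samples.
#' @export
evaluate_panel <- function(em, panel, labels, cfg = panel_eval_config()) {
  stopifnot(inherits(em, "expression_matrix"))
  absent <- setdiff(panel, rownames(em$values))
  if (length(absent))
    stop("panel transcript(s) missing from matrix: ",
         paste(utils::head(absent, 3L), collapse = ", "))
  if (!is.null(names(labels))) labels <- labels[colnames(em$values)]
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  x <- t(log2(em$values[panel, , drop = FALSE] + 1))
  colnames(x) <- make.names(colnames(x))
  yf <- factor(y, levels = c(0L, 1L))

  set.seed(cfg$seed)
  test <- stratified_split(y, cfg$split_fraction, cfg$stratified)
  xtr <- x[!test, , drop = FALSE]; ytr <- yf[!test]
  fold <- stratified_folds(as.integer(ytr) - 1L, cfg$cv_folds, cfg$stratified)
  cv_auc <- vapply(seq_len(cfg$cv_folds), function(k) {
    hold <- fold == k
    if (length(unique(ytr[hold])) < 2L) return(NA_real_)
    fit <- randomForest::randomForest(xtr[!hold, , drop = FALSE], ytr[!hold],
                                      ntree = cfg$n_trees)
    p <- stats::predict(fit, xtr[hold, , drop = FALSE], type = "prob")[, "1"]
    roc_curve(p, ytr[hold] == "1")$auc
  }, 0)
  fit <- randomForest::randomForest(xtr, ytr, ntree = cfg$n_trees)
  scores <- stats::predict(fit, x[test, , drop = FALSE], type = "prob")[, "1"]
  test_roc <- roc_curve(scores, y[test] == 1L)
  structure(list(auc_train_cv = mean(cv_auc, na.rm = TRUE),
                 auc_test = test_roc$auc,
                 roc = test_roc$roc,
                 scores = scores,
                 test_samples = colnames(em$values)[test]),
            class = "panel_eval_result")
}

#' @export
print.panel_eval_result <- function(x, ...) {
  cat(sprintf("<panel_eval_result> CV AUC %.3f | held-out AUC %.3f (%d test samples)\n",
              x$auc_train_cv, x$auc_test, length(x$test_samples)))
  invisible(x)
}
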