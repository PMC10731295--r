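# Kennard-Stone partitioning and classification reporting.

#' Kennard-Stone max-min sample selection
#'
#' Deterministic representative selection: the first two picks are the pair
#' at maximal Euclidean distance; every subsequent pick maximizes the
#' minimum distance to the already-selected points. All ties break to the
#' lowest row index.
#'
#' @param X n x p feature matrix.
#' @param n_select number of rows to select, `2 <= n_select <= n`.
#' @return integer vector of selected row indices, in selection order.
#' @export
kennard_stone <- function(X, n_select) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n_select < 2 || n_select > n) stopf("n_select must lie in [2, %d]", n)
  D <- as.matrix(stats::dist(X))
  if (max(D) == 0) stopf("all samples coincide; distances are all zero")
  idx <- which(D == max(D), arr.ind = TRUE)
  idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  first <- idx[order(idx[, 1], idx[, 2])[1], ]
  sel <- c(first[[1]], first[[2]])
  while (length(sel) < n_select) {
    cand <- setdiff(seq_len(n), sel)
    mind <- apply(D[cand, sel, drop = FALSE], 1, min)
    sel <- c(sel, cand[which.max(mind)])  # which.max: first (lowest index) on ties
  }
  as.integer(sel)
}

#' Kennard-Stone train/test split of a spectrum set
#'
#' Default (stratified) mode runs Kennard-Stone within each class, in SNV
#' space, and sends the selected points to the training set; the remainder
#' is the test set. The split is deterministic: repeated calls are
#' identical.
#'
#' @param ss a [spectrum_set()].
#' @param ratio training fraction (default 0.8, i.e. a 4:1 split).
#' @param stratified run the selection per class (default) or globally.
#' @param space `"snv"` (distances on SNV-corrected spectra) or `"raw"`.
#' @return a `ks_split`: `train_ids`, `test_ids`, `train_idx`, `test_idx`,
#'   `ratio`.
#' @export
ks_split <- function(ss, ratio = 0.8, stratified = TRUE, space = c("snv", "raw")) {
  stopifnot(inherits(ss, "spectrum_set"))
  space <- match.arg(space)
  if (ratio <= 0 || ratio >= 1) stopf("ratio must lie in (0, 1)")
  Xd <- if (space == "snv") snv(ss$spectra) else ss$spectra
  n <- nrow(Xd)
  if (stratified) {
    train_idx <- integer(0)
    for (cl in sort(unique(ss$labels))) {
      idx <- which(ss$labels == cl)
      n_tr <- round(ratio * length(idx))
      if (length(idx) < 2 || n_tr < 2 || n_tr >= length(idx))
        stopf("class %d too small for a stratified %g split", cl, ratio)
      sel <- kennard_stone(Xd[idx, , drop = FALSE], n_tr)
      train_idx <- c(train_idx, idx[sel])
    }
    train_idx <- sort(train_idx)
  } else {
    n_tr <- round(ratio * n)
    if (n_tr < 2 || n_tr >= n) stopf("dataset too small for a %g split", ratio)
    train_idx <- sort(kennard_stone(Xd, n_tr))
  }
  test_idx <- setdiff(seq_len(n), train_idx)
  structure(list(train_ids = ss$sample_ids[train_idx],
                 test_ids = ss$sample_ids[test_idx],
                 train_idx = train_idx, test_idx = test_idx,
                 ratio = ratio, stratified = stratified),
            class = "ks_split")
}

#' Classification report
#'
#' Multiclass accuracy (correct / total, the trace of the confusion matrix
#' over its sum) and per-class TP/TN/FP/FN from the one-vs-rest collapse of
#' the confusion matrix, with the per-class binary accuracy
#' `(TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param predictions predicted labels.
#' @param truth true labels (same length).
#' @param classes class set (default: sorted union of both).
#' @return a `classification_report`: `confusion_matrix` (truth in rows),
#'   `accuracy`, `per_class` data.frame, `n`.
#' @export
evaluate_predictions <- function(predictions, truth, classes = NULL) {
  if (length(predictions) != length(truth))
    stopf("predictions (%d) and truth (%d) lengths differ",
          length(predictions), length(truth))
  classes <- classes %||% sort(unique(c(predictions, truth)))
  if (!all(predictions %in% classes) || !all(truth %in% classes))
    stopf("labels outside the known class set")
  cm <- table(truth = factor(truth, classes), predicted = factor(predictions, classes))
  total <- sum(cm)
  per <- do.call(rbind, lapply(seq_along(classes), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- total - tp - fn - fp
    data.frame(class = classes[i], tp = tp, tn = tn, fp = fp, fn = fn,
               binary_accuracy = (tp + tn) / total)
  }))
  structure(list(confusion_matrix = cm,
                 accuracy = sum(diag(cm)) / total,
                 per_class = per, n = total),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> accuracy %.1f%% on %d samples\n",
              100 * x$accuracy, x$n))
  print(x$confusion_matrix)
  invisible(x)
}
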