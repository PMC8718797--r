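#' Random k-fold assignment of labelled pairs
#'
#' Partitions the pairs into `folds` subsets whose sizes differ by at most
#' one. Stratified by label by default (each fold gets a near-equal share
#' of positives and negatives), with `stratified = FALSE` for a plain
#' random split. Deterministic given the seed.
#'
#' @param labels 0/1 label vector.
#' @param folds number of folds (default 10).
#' @param seed RNG seed.
#' @param stratified stratify by label (default TRUE).
#' @return Integer fold id per pair, in `1:folds`.
#' @export
kfold_split <- function(labels, folds = 10, seed = 1, stratified = TRUE) {
  n <- length(labels)
  if (folds > n) stop("more folds than pairs")
  with_seed(seed, {
    fold <- integer(n)
    if (stratified) {
      # round-robin continues across classes so per-class AND total fold
      # sizes each differ by at most one
      ptr <- 0L
      for (cl in unique(labels)) {
        idx <- sample(which(labels == cl))
        fold[idx] <- ((ptr + seq_along(idx) - 1L) %% folds) + 1L
        ptr <- ptr + length(idx)
      }
    } else {
      fold[sample.int(n)] <- rep_len(seq_len(folds), n)
    }
    fold
  })
}

#' Confusion counts at a decision threshold
#'
#' @param scores predicted probabilities.
#' @param labels 0/1 labels.
#' @param threshold decision threshold (default 0.5).
#' @return List with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(scores, labels, threshold = 0.5) {
  pred <- as.integer(scores >= threshold)
  list(TP = sum(pred == 1 & labels == 1),
       TN = sum(pred == 0 & labels == 0),
       FP = sum(pred == 1 & labels == 0),
       FN = sum(pred == 0 & labels == 1))
}

#' Confusion-matrix classification metrics
#'
#' Accuracy, Recall, F1 (`2 TP / (2 TP + FP + FN)`) and the Matthews
#' correlation coefficient. A metric whose denominator is zero is
#' undefined and reported as `NaN` with a warning.
#'
#' @param counts list with `TP`, `TN`, `FP`, `FN` (see
#'   [confusion_counts()]).
#' @return Named numeric vector `ACC`, `Recall`, `F1`, `MCC`.
#' @export
classification_metrics <- function(counts) {
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  tot <- TP + TN + FP + FN
  if (tot == 0) stop("empty confusion counts")
  safe <- function(num, den, what) {
    if (den == 0) { warning(what, " undefined (zero denominator)"); NaN }
    else num / den
  }
  c(ACC = (TP + TN) / tot,
    Recall = safe(TP, TP + FN, "Recall"),
    F1 = safe(2 * TP, 2 * TP + FP + FN, "F1"),
    MCC = safe(TP * TN - FP * FN,
               sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN),
               "MCC"))
}

#' ROC curve and AUC by the trapezoidal rule
#'
#' Sweeps every distinct score as a threshold, accumulating TPR/FPR, and
#' integrates by trapezoids; with tied scores grouped this equals the
#' Mann-Whitney pair statistic with ties counted one half.
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels 0/1 labels; both classes required.
#' @return List: `auc` and `roc` (data frame `fpr`, `tpr`, `threshold`).
#' @export
roc_auc <- function(scores, labels) {
  if (length(unique(labels)) < 2) stop("both classes required for ROC")
  ord <- order(-scores)
  s <- scores[ord]; y <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- !duplicated(grp, fromLast = TRUE)  # end of each tie group
  P <- sum(labels); N <- sum(1 - labels)
  tpr <- c(0, tp[last] / P); fpr <- c(0, fp[last] / N)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(auc = auc,
       roc = data.frame(fpr = fpr, tpr = tpr,
                        threshold = c(Inf, s[last])))
}

#' Cross-validated evaluation of the cascade classifier
#'
#' Splits the labelled pairs into folds, trains the GBDT-to-LR cascade on
#' the other folds and evaluates on the held-out one; reports the
#' per-fold and mean metrics and a mean ROC obtained by vertical
#' averaging of the fold ROC curves on a common FPR grid.
#'
#' @param X feature matrix (one row per labelled pair).
#' @param labels 0/1 labels.
#' @param folds number of folds (default 10).
#' @param seed RNG seed for the split.
#' @param stratified stratify the split by label (default TRUE).
#' @param threshold decision threshold for the count metrics (default
#'   0.5).
#' @param ... passed to [gbdt_lr_fit()] (`n_trees`, `alpha`, `max_depth`,
#'   `min_leaf`, `l2`, `max_steps`).
#' @return List: `per_fold` (data frame, one row per fold), `mean` (named
#'   vector), `mean_roc` (data frame `fpr`, `tpr`).
#' @export
cross_validate <- function(X, labels, folds = 10, seed = 1,
                           stratified = TRUE, threshold = 0.5, ...) {
  X <- as.matrix(X)
  fold <- kfold_split(labels, folds = folds, seed = seed,
                      stratified = stratified)
  grid <- seq(0, 1, by = 0.01)
  rows <- vector("list", folds)
  tpr_grid <- matrix(NA_real_, folds, length(grid))
  for (f in seq_len(folds)) {
    tr <- fold != f; te <- !tr
    model <- gbdt_lr_fit(X[tr, , drop = FALSE], labels[tr], ...)
    p <- predict(model, X[te, , drop = FALSE])
    met <- classification_metrics(confusion_counts(p, labels[te],
                                                   threshold))
    rc <- roc_auc(p, labels[te])
    tpr_grid[f, ] <- approx(rc$roc$fpr, rc$roc$tpr, xout = grid,
                            ties = max, rule = 2)$y
    rows[[f]] <- data.frame(fold = f, t(met), AUC = rc$auc)
  }
  per_fold <- do.call(rbind, rows)
  means <- colMeans(per_fold[, -1, drop = FALSE])
  list(per_fold = per_fold, mean = means,
       mean_roc = data.frame(fpr = grid, tpr = colMeans(tpr_grid)))
}

#' Write per-fold metrics and mean as TSV
#'
#' @param cv a [cross_validate()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(cv, path) {
  tab <- rbind(cv$per_fold,
               data.frame(fold = "mean", t(cv$mean), check.names = FALSE))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
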