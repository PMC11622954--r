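#' Classification metrics from confusion counts
#'
#' Computes accuracy, precision, recall and F-score from binary confusion
#' counts:
#' \deqn{Accuracy = (T_n + T_p) / (T_n + F_n + T_p + F_p)}
#' \deqn{Precision = T_p / (F_p + T_p), \quad Recall = T_p / (F_n + T_p)}
#' \deqn{F = 2 \cdot Precision \cdot Recall / (Precision + Recall)}
#'
#' @param counts named list or vector with nonnegative integer entries
#'   `Tp`, `Tn`, `Fp`, `Fn`.
#' @return named list with `accuracy`, `precision`, `recall`, `f_score`.
#'   A zero denominator raises an error naming the undefined metric.
#' @seealso [macro_classification_metrics()] for multi-class input.
#' @export
classification_metrics <- function(counts) {
  cn <- c("Tp", "Tn", "Fp", "Fn")
  if (!all(cn %in% names(counts)))
    abort("counts must have entries Tp, Tn, Fp, Fn")
  k <- vapply(cn, function(nm) as.numeric(counts[[nm]]), numeric(1))
  if (any(k < 0) || any(k != round(k)))
    abort("confusion counts must be nonnegative integers")
  total <- sum(k)
  if (total == 0) abort("undefined metric 'accuracy': empty confusion counts")
  if (k["Tp"] + k["Fp"] == 0) abort("undefined metric 'precision': Tp + Fp = 0")
  if (k["Tp"] + k["Fn"] == 0) abort("undefined metric 'recall': Tp + Fn = 0")
  precision <- k[["Tp"]] / (k[["Tp"]] + k[["Fp"]])
  recall <- k[["Tp"]] / (k[["Tp"]] + k[["Fn"]])
  if (precision + recall == 0)
    abort("undefined metric 'f_score': precision + recall = 0")
  list(
    accuracy = (k[["Tn"]] + k[["Tp"]]) / total,
    precision = precision,
    recall = recall,
    f_score = 2 * precision * recall / (precision + recall)
  )
}

#' Confusion counts for one positive class
#'
#' @param truth,pred equal-length label vectors.
#' @param positive label treated as the positive class.
#' @return list with `Tp`, `Tn`, `Fp`, `Fn`.
#' @export
confusion_counts <- function(truth, pred, positive) {
  if (length(truth) != length(pred)) abort("truth and pred lengths differ")
  tp <- truth == positive
  pp <- pred == positive
  list(Tp = sum(tp & pp), Tn = sum(!tp & !pp),
       Fp = sum(!tp & pp), Fn = sum(tp & !pp))
}

#' Macro-averaged one-vs-rest classification metrics
#'
#' Each class in turn is taken as positive, binary metrics are computed from
#' its one-vs-rest confusion counts, and the per-class values are averaged
#' with equal weight.
#'
#' @inheritParams confusion_counts
#' @return list with macro `accuracy`, `precision`, `recall`, `f_score` and a
#'   `per_class` data frame.
#' @export
macro_classification_metrics <- function(truth, pred) {
  classes <- sort(unique(truth))
  rows <- lapply(classes, function(cl) {
    m <- classification_metrics(confusion_counts(truth, pred, cl))
    data.frame(class = cl, accuracy = m$accuracy, precision = m$precision,
               recall = m$recall, f_score = m$f_score)
  })
  per_class <- do.call(rbind, rows)
  list(accuracy = mean(per_class$accuracy),
       precision = mean(per_class$precision),
       recall = mean(per_class$recall),
       f_score = mean(per_class$f_score),
       per_class = per_class)
}

#' Regression error statistics
#'
#' Mean absolute error, mean squared error and root mean squared error of a
#' prediction vector against ground truth. Absolute differences are used for
#' MAE so that it is nonnegative by construction.
#'
#' @param truth,pred equal-length numeric vectors.
#' @return list with `mae`, `mse`, `rmse`.
#' @export
error_stats <- function(truth, pred) {
  if (length(truth) != length(pred)) abort("truth and pred lengths differ")
  if (length(truth) < 1) abort("need at least one observation")
  d <- as.numeric(truth) - as.numeric(pred)
  mse <- mean(d^2)
  list(mae = mean(abs(d)), mse = mse, rmse = sqrt(mse))
}

#' Dice coefficient and intersection-over-union of two masks
#'
#' \deqn{Dice = 2|A \cap B| / (|A| + |B|), \quad IoU = |A \cap B| / |A \cup B|}
#' Two empty masks agree perfectly by convention: both scores are 1.
#'
#' @param a,b logical vectors/matrices of identical shape.
#' @return list with `dice` and `iou`.
#' @export
dice_iou <- function(a, b) {
  if (!identical(dim(a), dim(b)) || length(a) != length(b))
    abort("mask shapes differ")
  a <- as.logical(a); b <- as.logical(b)
  inter <- sum(a & b)
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(list(dice = 1, iou = 1))
  list(dice = 2 * inter / (sa + sb), iou = inter / (sa + sb - inter))
}

#' Stratified k-fold assignment
#'
#' Samples of each class are shuffled (seeded) and dealt round-robin into `k`
#' folds, so every fold's class proportions are within one sample of the
#' global proportions.
#'
#' @param labels class label per sample.
#' @param k number of folds (each class must have at least `k` members).
#' @param seed RNG seed for the per-class shuffles.
#' @return integer vector of fold ids in `1:k`, one per sample.
#' @export
stratified_kfold <- function(labels, k, seed = 1L) {
  if (k < 2) abort("k must be at least 2")
  tab <- table(labels)
  if (any(tab < k))
    abort("class '", names(tab)[which.min(tab)], "' has fewer than k members")
  folds <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in names(tab)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}
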