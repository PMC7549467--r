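# Rank (Mann-Whitney) AUC of `score` for the positive indicator `pos`.
auc_rank <- function(score, pos) {
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics on a score matrix
#'
#' Computes the evaluation bundle used throughout the package: accuracy
#' (correct predictions over all predictions), macro-averaged precision and
#' recall, the confusion matrix, and AUC. For two classes the AUC is the
#' standard ROC AUC of the positive-class score; for three or more it is the
#' macro average of the one-vs-rest AUCs. Because the class labels are
#' imbalanced by construction, AUC is the headline metric.
#'
#' @param truth factor of true labels.
#' @param scores numeric matrix, one column per factor level of `truth`
#'   (column order must match `levels(truth)`); probabilities or arbitrary
#'   monotone decision scores. Predicted class is the column argmax.
#' @return list of class `eval_metrics`: `auc`, `accuracy`, `precision`,
#'   `recall` (fractions) and `confusion` (true x predicted counts).
#' @export
classification_metrics <- function(truth, scores) {
  truth <- as.factor(truth)
  lev <- levels(truth)
  if (!is.matrix(scores) || ncol(scores) != length(lev) ||
      nrow(scores) != length(truth) || !length(truth)) {
    stop_invalid("`scores` must be a nonempty matrix with one column per class")
  }
  pred <- factor(lev[max.col(scores, ties.method = "first")], levels = lev)
  confusion <- table(truth = truth, predicted = pred)
  accuracy <- sum(diag(confusion)) / sum(confusion)
  prec <- vapply(lev, function(l) {
    denom <- sum(pred == l)
    if (denom == 0) 0 else sum(pred == l & truth == l) / denom
  }, numeric(1))
  rec <- vapply(lev, function(l) {
    denom <- sum(truth == l)
    if (denom == 0) 0 else sum(pred == l & truth == l) / denom
  }, numeric(1))
  if (length(lev) == 2L) {
    auc <- auc_rank(scores[, 2L], truth == lev[2L])
  } else {
    auc <- mean(vapply(seq_along(lev), function(k) {
      auc_rank(scores[, k], truth == lev[k])
    }, numeric(1)), na.rm = TRUE)
  }
  structure(
    list(auc = auc, accuracy = accuracy,
         precision = mean(prec), recall = mean(rec),
         confusion = confusion),
    class = "eval_metrics"
  )
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf("AUC %.4f | accuracy %.4f | precision %.4f | recall %.4f\n",
              x$auc, x$accuracy, x$precision, x$recall))
  print(x$confusion)
  invisible(x)
}

#' Stratified or participant-grouped 80/20 split
#'
#' Default: stratified by class at the recording level — within each class a
#' fraction `frac` of recordings (rounded, at least one on each side) is
#' assigned to training. With `groups` given (participant ids), whole
#' participants are assigned to one side, stratified by their majority
#' class, which prevents subject leakage between training and validation.
#'
#' @param labels factor of class labels.
#' @param groups optional vector of group (participant) ids, same length.
#' @param frac training fraction (default 0.8).
#' @param seed integer seed.
#' @return list of class `data_split` with integer index vectors `train`
#'   and `val`. Errors with a split-error if any class is missing from
#'   either partition.
#' @export
make_split <- function(labels, groups = NULL, frac = 0.8, seed = 1L) {
  labels <- as.factor(labels)
  n <- length(labels)
  if (!n) stop_split("empty dataset")
  if (nlevels(droplevels(labels)) < 2L) {
    stop_split("need at least two classes to split")
  }
  train <- integer(0)
  with_seed(seed, {
    if (is.null(groups)) {
      for (l in levels(labels)) {
        idx <- which(labels == l)
        if (length(idx) < 2L) {
          stop_split(paste0("class ", l, " has fewer than 2 examples"))
        }
        k <- min(length(idx) - 1L, max(1L, round(frac * length(idx))))
        train <- c(train, sample(idx, k))
      }
    } else {
      if (length(groups) != n) stop_invalid("`groups` length mismatch")
      gl <- tapply(as.character(labels), groups, function(x) {
        names(sort(table(x), decreasing = TRUE))[1]
      })
      gnames <- names(gl)
      gtrain <- character(0)
      for (l in unique(gl)) {
        gx <- gnames[gl == l]
        if (length(gx) < 2L) {
          stop_split(paste0("class ", l, " covered by fewer than 2 groups"))
        }
        k <- min(length(gx) - 1L, max(1L, round(frac * length(gx))))
        gtrain <- c(gtrain, sample(gx, k))
      }
      train <- which(groups %in% gtrain)
    }
  })
  train <- sort(train)
  val <- setdiff(seq_len(n), train)
  if (!all(levels(droplevels(labels)) %in% labels[train]) ||
      !all(levels(droplevels(labels)) %in% labels[val])) {
    stop_split("a class is absent from one partition")
  }
  structure(list(train = train, val = sort(val)), class = "data_split")
}
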