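# Train/test splitting and ROC/AUC evaluation.

#' Train/test split plan
#'
#' Deterministic (seeded) split into a training and a test part. By default
#' the split is stratified by the outcome so both parts keep the overall
#' prevalence; the training count per stratum is the half-up rounding of
#' `fraction` times the stratum size (801 observations at fraction 0.7 give
#' 561 training and 240 test rows).
#'
#' @param y outcome vector (defines `n` and the strata when stratified).
#' @param fraction training fraction in (0,1); default 0.7.
#' @param seed integer seed; the caller's RNG state is left untouched.
#' @param stratify stratify by `y` (default TRUE).
#' @return list of class `split_plan` with integer index vectors `train` and
#'   `test` (disjoint, exhaustive).
#' @export
split_data <- function(y, fraction = 0.7, seed = NULL, stratify = TRUE) {
  n <- length(y)
  stopifnot(n >= 10, fraction > 0, fraction < 1)
  train <- integer(0)
  with_seed(seed, {
    if (stratify) {
      for (cl in unique(y)) {
        idx <- which(y == cl)
        k <- floor(length(idx) * fraction + 0.5)
        train <- c(train, sample(idx, k))
      }
    } else {
      train <- sample.int(n, floor(n * fraction + 0.5))
    }
  })
  train <- sort(train)
  test <- setdiff(seq_len(n), train)
  if (!stratify && length(unique(y)) == 2 &&
      (length(unique(y[train])) < 2 || length(unique(y[test])) < 2))
    stop("a class is absent from one part of the unstratified split")
  structure(list(train = train, test = test, fraction = fraction,
                 seed = seed), class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat("split_plan: ", length(x$train), " train / ", length(x$test),
      " test (fraction ", x$fraction, ")\n", sep = "")
  invisible(x)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a randomly chosen
#' positive scores above a randomly chosen negative, ties counted one half.
#' Identical to the trapezoidal area under the empirical ROC curve; constant
#' scores give exactly 0.5.
#'
#' @param scores numeric predictions (any strictly increasing transform of
#'   them gives the same AUC).
#' @param labels binary 0/1 outcomes.
#' @return the AUC, a real in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  labels <- check_binary_outcome(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present to compute AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC curve
#'
#' Sweeps every distinct score threshold and records the false and true
#' positive rates; the stored curve runs from (0,0) to (1,1) with
#' non-decreasing coordinates, and its trapezoidal area equals [auc()].
#'
#' @inheritParams auc
#' @return data frame of class `roc_curve` with columns `threshold`, `fpr`,
#'   `tpr`; the trapezoidal area is attached as attribute `"auc"`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- check_binary_outcome(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1) / n1, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0) / n0, 0)
  out <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                    tpr = c(0, tpr))
  if (out$fpr[nrow(out)] != 1 || out$tpr[nrow(out)] != 1)
    out <- rbind(out, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  area <- sum(diff(out$fpr) * (utils::head(out$tpr, -1) +
                                 utils::tail(out$tpr, -1)) / 2)
  structure(out, auc = area, class = c("roc_curve", class(out)))
}
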