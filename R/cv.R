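# Cross-validated early stopping.

# Stratified fold labels: within each outcome class, observations are
# shuffled and dealt round-robin into folds, so every training partition keeps
# (almost exactly) the overall prevalence.
make_folds <- function(y, folds, seed, stratify = TRUE) {
  n <- length(y)
  lab <- integer(n)
  with_seed(seed, {
    if (stratify) {
      for (cl in unique(y)) {
        idx <- which(y == cl)
        if (length(idx) < folds)
          stop("a class has fewer observations (", length(idx),
               ") than folds (", folds, "); stratified folds impossible")
        lab[idx] <- sample(rep_len(seq_len(folds), length(idx)))
      }
    } else {
      lab <- sample(rep_len(seq_len(folds), n))
    }
  })
  lab
}

# Shared CV driver. `f_init` optionally carries a fixed full-data linear
# predictor from an earlier K-step stage (held fixed across folds).
cv_risk_curve <- function(design, y, learners, eta, folds, cv_max, seed,
                          family, offset, f_init = NULL) {
  X <- design$values
  lab <- make_folds(y, folds, seed, stratify = (family == "binomial"))
  curves <- matrix(NA_real_, folds, cv_max + 1L)
  for (k in seq_len(folds)) {
    tr <- which(lab != k); te <- which(lab == k)
    if (family == "binomial" && length(unique(y[tr])) < 2L)
      stop("training fold ", k, " lost a class; use fewer folds")
    if (is.null(f_init)) {
      f0 <- init_offset(y[tr], family, offset)
      fv0 <- f0
    } else {
      f0 <- f_init[tr]
      fv0 <- f_init[te]
    }
    res <- boost_engine(X[tr, , drop = FALSE], y[tr], learners, eta, cv_max,
                        f0, family,
                        Xv = X[te, , drop = FALSE], yv = y[te], fv0 = fv0)
    curves[k, ] <- res$valid_path
  }
  colMeans(curves)
}

#' Choose the stopping iteration by k-fold cross-validation
#'
#' Fits the boosting path on each of `folds` stratified training partitions,
#' evaluates the out-of-fold mean negative log-likelihood per observation
#' after every iteration m = 0..`cv_max`, and returns the m minimizing the
#' fold-averaged risk (ties broken toward the smallest m, favouring sparsity).
#'
#' @inheritParams boost
#' @param folds number of CV folds (default 10).
#' @param cv_max largest iteration count searched.
#' @param seed integer seed driving the fold assignment (stratified by `y` for
#'   the binomial family); the caller's RNG state is left untouched.
#' @return the selected integer `mstop`, with the fold-mean risk curve
#'   attached as attribute `"cv_risk"` (length `cv_max + 1`, element 1 = m 0).
#' @export
cv_mstop <- function(design, y, learners, eta = 0.1, folds = 10,
                     cv_max = 1000, seed = NULL,
                     offset = c("logit-mean", "zero"),
                     family = c("binomial", "gaussian")) {
  family <- match.arg(family)
  offset <- match.arg(offset)
  stopifnot(folds >= 2)
  if (family == "binomial") y <- check_binary_outcome(y)
  curve <- cv_risk_curve(design, y, learners, eta, folds, cv_max, seed,
                         family, offset)
  m <- which.min(curve) - 1L
  structure(m, cv_risk = curve)
}
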