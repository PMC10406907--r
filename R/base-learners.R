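# Ridge-penalized least-squares base-learners.
#
# A base-learner is a column block of the design matrix plus the ridge
# regression on it. Its complexity is measured by the effective degrees of
# freedom df(lambda) = tr(2S - S'S) of the ridge hat matrix
# S = X(X'X + lambda I)^{-1} X', and every learner's penalty is calibrated so
# that all learners offered to the selection step have equal df: the fairness
# device that lets one-column binary blocks compete with multi-column
# categorical or group blocks.

rank_tol <- 1e-10

block_eigenvalues <- function(block) {
  XtX <- crossprod(as.matrix(block))
  d <- eigen(XtX, symmetric = TRUE, only.values = TRUE)$values
  pmax(d, 0)
}

df_from_eigen <- function(d, lambda) {
  if (is.infinite(lambda)) return(0)
  if (lambda == 0) return(sum(d > rank_tol * max(d, rank_tol)))
  s <- d / (d + lambda)
  sum(2 * s - s^2)
}

#' Effective degrees of freedom of a ridge base-learner
#'
#' Computes df(lambda) = tr(2S - S'S) for S = X(X'X + lambda I)^{-1}X', via
#' the eigenvalues d_i of X'X: df = sum_i \[2 d_i/(d_i+lambda) -
#' (d_i/(d_i+lambda))^2\]. At lambda = 0 this equals the block rank; it
#' decreases strictly with lambda and tends to 0 (lambda = Inf returns 0 by
#' convention).
#'
#' @param block n x k numeric matrix (one base-learner's columns).
#' @param lambda ridge penalty, nonnegative (may be `Inf`).
#' @return the effective degrees of freedom, a real in \[0, rank\].
#' @export
df_from_lambda <- function(block, lambda) {
  stopifnot(lambda >= 0)
  df_from_eigen(block_eigenvalues(block), lambda)
}

lambda_from_eigen <- function(d, target_df, tol = 1e-10) {
  rank <- sum(d > rank_tol * max(d, rank_tol))
  if (target_df <= 0 || target_df > rank + tol)
    stop("target_df must lie in (0, rank]; rank = ", rank)
  if (abs(target_df - rank) < tol) return(0)
  # bisection on log(lambda); df is strictly decreasing in lambda
  lo <- log(max(d) * 1e-12); hi <- log(max(d) * 1e4)
  while (df_from_eigen(d, exp(hi)) > target_df) hi <- hi + 5
  while (df_from_eigen(d, exp(lo)) < target_df) lo <- lo - 5
  for (i in 1:300) {
    mid <- (lo + hi) / 2
    val <- df_from_eigen(d, exp(mid))
    if (abs(val - target_df) < tol) return(exp(mid))
    if (val > target_df) lo <- mid else hi <- mid
  }
  exp((lo + hi) / 2)
}

#' Calibrate the ridge penalty to a target degrees of freedom
#'
#' Inverts [df_from_lambda()] by bracketed bisection on log(lambda), exploiting
#' strict monotonicity. `target_df` equal to the block rank returns lambda = 0
#' exactly; for a single column with sum of squares t the closed form is
#' lambda = t (1 - s)/s with s = 1 - sqrt(1 - target_df).
#'
#' @inheritParams df_from_lambda
#' @param target_df requested degrees of freedom in (0, rank\].
#' @param tol convergence tolerance on df (default 1e-10).
#' @return the calibrated penalty `lambda >= 0`.
#' @export
lambda_from_df <- function(block, target_df, tol = 1e-10) {
  lambda_from_eigen(block_eigenvalues(block), target_df, tol)
}

#' Construct a calibrated ridge base-learner
#'
#' @param design a `boost_design`.
#' @param id term id; defaults to a block id in `design$blocks`, in which case
#'   `cols` is taken from that block.
#' @param cols column indices of the learner's block (overrides the block
#'   lookup, e.g. for group learners spanning several variables).
#' @param target_df target degrees of freedom; 0 marks the learner excluded
#'   (lambda = Inf, never selectable). Requests exceeding the block rank are
#'   truncated to the rank (rank 0 blocks are excluded) with a warning.
#' @param kind one of "individual", "group", "interaction".
#' @return object of class `ridge_learner` holding the column set, calibrated
#'   lambda, attained df and the small matrices reused at every boosting step.
#' @export
ridge_learner <- function(design, id, cols = NULL, target_df = 1,
                          kind = "individual") {
  stopifnot(inherits(design, "boost_design"))
  if (is.null(cols)) {
    blk <- design$blocks[[id]]
    if (is.null(blk)) stop("no design block with id '", id, "'")
    cols <- blk$cols
  }
  X <- design$values[, cols, drop = FALSE]
  XtX <- crossprod(X)
  d <- pmax(eigen(XtX, symmetric = TRUE, only.values = TRUE)$values, 0)
  rank <- sum(d > rank_tol * max(d, rank_tol))
  excluded <- FALSE
  if (target_df > rank) {
    warning("learner '", id, "': target df ", target_df,
            " exceeds block rank ", rank, "; truncated")
    target_df <- rank
  }
  if (target_df == 0) {
    lambda <- Inf
    excluded <- TRUE
  } else {
    lambda <- lambda_from_eigen(d, target_df)
  }
  structure(list(id = id, cols = as.integer(cols), kind = kind,
                 target_df = target_df, lambda = lambda,
                 df = df_from_eigen(d, lambda), spectrum = d, rank = rank,
                 XtX = XtX, excluded = excluded),
            class = "ridge_learner")
}

#' @export
print.ridge_learner <- function(x, ...) {
  cat("ridge_learner '", x$id, "' (", x$kind, "): ", length(x$cols),
      " column(s), df = ", format(x$df, digits = 4), ", lambda = ",
      format(x$lambda, digits = 4),
      if (x$excluded) " [excluded]", "\n", sep = "")
  invisible(x)
}

# (X'X + lambda I)^{-1}, falling back to the Moore-Penrose pseudoinverse when
# lambda = 0 on a rank-deficient block (the penalized LS fit is then the
# minimum-norm projection onto the block's column space).
penalized_inverse <- function(XtX, lambda) {
  k <- ncol(XtX)
  if (is.finite(lambda) && lambda > 0) return(solve(XtX + diag(lambda, k)))
  e <- eigen(XtX, symmetric = TRUE)
  keep <- e$values > rank_tol * max(e$values, rank_tol)
  if (!any(keep)) return(matrix(0, k, k))
  V <- e$vectors[, keep, drop = FALSE]
  V %*% (t(V) / e$values[keep])
}

#' Fit a base-learner to pseudo-residuals
#'
#' Penalized least squares of the working response `u` on the learner's block:
#' coefficients (X'X + lambda I)^{-1} X'u, plus the fitted values and their sum
#' of squared errors to `u` (the quantity the selection step compares across
#' learners). An excluded learner (lambda = Inf) returns zero coefficients and
#' SSE = sum(u^2).
#'
#' @param learner a `ridge_learner`.
#' @param block the learner's n x k column block.
#' @param u numeric working response (negative-gradient vector).
#' @return list with `coef`, `fitted`, `sse`.
#' @export
fit_base_learner <- function(learner, block, u) {
  stopifnot(all(is.finite(u)))
  block <- as.matrix(block)
  if (is.infinite(learner$lambda)) {
    return(list(coef = numeric(ncol(block)), fitted = numeric(length(u)),
                sse = sum(u^2)))
  }
  A <- penalized_inverse(crossprod(block), learner$lambda)
  beta <- unname(drop(A %*% crossprod(block, u)))
  fitted <- drop(block %*% beta)
  list(coef = beta, fitted = fitted, sse = sum((u - fitted)^2))
}
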