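# Functional gradient descent with component-wise selection.
#
# Per iteration: evaluate the negative gradient of the loss at the current fit
# (the pseudo-residuals u), fit every base-learner to u by penalized least
# squares, select the learner whose fit has the smallest sum of squared errors
# to u, and move the fit a step of length eta along that learner's fitted
# values. The intercept lives entirely in the offset and is never selectable.

#' Negative gradient of the loss (pseudo-residuals)
#'
#' For the binomial negative log-likelihood under the logit link the negative
#' gradient at linear predictor `f` is `y - 1/(1 + exp(-f))`, i.e. observed
#' minus predicted probability. The Gaussian variant (`y - f`) exists for
#' closed-form checks against ordinary least squares.
#'
#' @param y numeric outcome (0/1 for binomial).
#' @param f numeric linear predictor, same length as `y`.
#' @param family "binomial" (default) or "gaussian".
#' @return numeric vector of pseudo-residuals.
#' @export
negative_gradient <- function(y, f, family = c("binomial", "gaussian")) {
  family <- match.arg(family)
  if (family == "binomial") y - stats::plogis(f) else y - f
}

#' Loss-minimizing constant offset
#'
#' The boosting fit is initialized at the constant that minimizes the loss:
#' the log-odds of the training prevalence for the binomial loss (`log(ybar /
#' (1 - ybar))`), the mean for the Gaussian test mode, or 0 when
#' `type = "zero"`.
#'
#' @inheritParams negative_gradient
#' @param type "logit-mean" (default) or "zero".
#' @return a single numeric offset on the link scale.
#' @export
init_offset <- function(y, family = c("binomial", "gaussian"),
                        type = c("logit-mean", "zero")) {
  family <- match.arg(family)
  type <- match.arg(type)
  if (type == "zero") return(0)
  if (family == "binomial") {
    y <- check_binary_outcome(y)
    if (length(unique(y)) < 2L)
      stop("outcome has a single class; offset undefined")
    stats::qlogis(mean(y))
  } else {
    mean(y)
  }
}

# Precompute per-learner Gram matrices on the rows actually fitted. Learners
# keep the lambda calibrated on the full training design; only the cross
# products are recomputed (e.g. inside CV folds).
prepare_learners <- function(X, learners) {
  ids <- vapply(learners, `[[`, "", "id")
  k <- vapply(learners, function(l) length(l$cols), 0L)
  excluded <- vapply(learners, `[[`, TRUE, "excluded")
  scal <- which(k == 1L & !excluded)
  gen <- which(k > 1L & !excluded)
  sc <- NULL
  if (length(scal)) {
    cols <- vapply(learners[scal], function(l) l$cols, 0L)
    xtx <- colSums(X[, cols, drop = FALSE]^2)
    lam <- vapply(learners[scal], `[[`, 0, "lambda")
    sc <- list(idx = scal, cols = cols, xtx = xtx, denom = xtx + lam)
  }
  ge <- lapply(gen, function(r) {
    l <- learners[[r]]
    XtX <- crossprod(X[, l$cols, drop = FALSE])
    list(idx = r, cols = l$cols, XtX = XtX,
         Minv = penalized_inverse(XtX, l$lambda))
  })
  list(ids = ids, scalar = sc, general = ge, excluded = excluded,
       any_selectable = length(scal) + length(gen) > 0)
}

# Core loop shared by boost(), cv_mstop() and kstep_boost(). `f0` is the full
# starting linear predictor (offset and, for later K-step stages, the previous
# stages' fit). Optionally tracks a validation risk path on (Xv, yv, fv0).
boost_engine <- function(X, y, learners, eta, mstop, f0, family,
                         Xv = NULL, yv = NULL, fv0 = NULL) {
  n <- nrow(X)
  risk <- risk_fun(family)
  pre <- prepare_learners(X, learners)
  f <- if (length(f0) == 1L) rep(f0, n) else f0
  agg <- numeric(ncol(X))
  sel <- integer(mstop)
  increments <- vector("list", mstop)
  risk_path <- numeric(mstop + 1L)
  risk_path[1L] <- risk(y, f)
  fv <- NULL
  valid_path <- NULL
  if (!is.null(Xv)) {
    fv <- if (length(fv0) == 1L) rep(fv0, nrow(Xv)) else fv0
    valid_path <- numeric(mstop + 1L)
    valid_path[1L] <- risk(yv, fv) / nrow(Xv)
  }
  if (!pre$any_selectable || mstop == 0L) {
    return(list(f = f, aggregated = agg, selected = integer(0),
                increments = list(), risk_path = risk_path[1L],
                valid_path = if (is.null(valid_path)) NULL else valid_path[1L],
                learner_ids = pre$ids, mstop = 0L))
  }
  R <- length(learners)
  for (m in seq_len(mstop)) {
    u <- negative_gradient(y, f, family)
    XtU <- drop(crossprod(X, u))
    uu <- sum(u^2)
    sse_all <- rep(Inf, R)
    gen_beta <- vector("list", R)
    sc <- pre$scalar
    if (!is.null(sc)) {
      beta_sc <- XtU[sc$cols] / sc$denom
      sse_all[sc$idx] <- uu - beta_sc * (2 * XtU[sc$cols] - beta_sc * sc$xtx)
    }
    for (g in pre$general) {
      b <- drop(g$Minv %*% XtU[g$cols])
      gen_beta[[g$idx]] <- b
      sse_all[g$idx] <- uu - 2 * sum(b * XtU[g$cols]) + sum(b * (g$XtX %*% b))
    }
    best <- which.min(sse_all)  # ties break toward the lowest learner index
    if (!is.null(gen_beta[[best]])) {
      best_beta <- gen_beta[[best]]
      best_cols <- learners[[best]]$cols
    } else {
      j <- match(best, sc$idx)
      best_beta <- beta_sc[j]
      best_cols <- sc$cols[j]
    }
    step <- eta * best_beta
    f <- f + drop(X[, best_cols, drop = FALSE] %*% step)
    agg[best_cols] <- agg[best_cols] + step
    sel[m] <- best
    increments[[m]] <- best_beta
    risk_path[m + 1L] <- risk(y, f)
    if (!is.null(Xv)) {
      fv <- fv + drop(Xv[, best_cols, drop = FALSE] %*% step)
      valid_path[m + 1L] <- risk(yv, fv) / nrow(Xv)
    }
  }
  list(f = f, aggregated = agg, selected = sel, increments = increments,
       risk_path = risk_path, valid_path = valid_path,
       learner_ids = pre$ids, mstop = mstop)
}

#' Component-wise gradient boosting
#'
#' Runs `mstop` iterations of functional gradient descent over a set of
#' calibrated ridge base-learners. The returned fit records the selection
#' path, the per-step coefficient increments, the aggregated coefficients, and
#' the in-sample risk (negative log-likelihood) after every step.
#'
#' @param design a `boost_design` (training rows).
#' @param y numeric outcome vector (0/1 for the binomial family).
#' @param learners list of [ridge_learner()] objects over `design`'s columns.
#' @param eta learning rate in (0,1]; default 0.1 (1 admits exact one-step least-squares checks in the Gaussian test mode).
#' @param mstop number of boosting iterations (0 gives the offset-only model).
#' @param offset "logit-mean" (default) or "zero"; see [init_offset()].
#' @param family "binomial" (default) or "gaussian" (closed-form test mode).
#' @return an object of class `boost_fit`; see Details. `fitted(fit)` equals
#'   `fit$offset + design$values %*% fit$aggregated`.
#' @details If every learner is excluded (df 0) the offset-only fit is
#'   returned with a warning and an empty selection path.
#' @export
boost <- function(design, y, learners, eta = 0.1, mstop = 100,
                  offset = c("logit-mean", "zero"),
                  family = c("binomial", "gaussian")) {
  family <- match.arg(family)
  offset <- match.arg(offset)
  stopifnot(inherits(design, "boost_design"), eta > 0, eta <= 1, mstop >= 0)
  if (family == "binomial") y <- check_binary_outcome(y)
  f0 <- init_offset(y, family, offset)
  pre_ok <- any(!vapply(learners, `[[`, TRUE, "excluded"))
  if (!pre_ok)
    warning("all base-learners are excluded; returning the offset-only fit")
  res <- boost_engine(design$values, y, learners, eta, mstop, f0, family)
  new_boost_fit(res, design, learners, y, eta, f0, family)
}

new_boost_fit <- function(res, design, learners, y, eta, offset, family,
                          step_label = NULL) {
  ids <- vapply(learners, `[[`, "", "id")
  structure(list(
    offset = offset,
    selection_path = ids[res$selected],
    increments = res$increments,
    selected_index = res$selected,
    aggregated = stats::setNames(res$aggregated, colnames(design$values)),
    risk_path = res$risk_path,
    fitted = res$f,
    eta = eta, family = family, y = y,
    learners = learners, design = design,
    mstop = res$mstop, step_label = step_label),
    class = "boost_fit")
}

#' @export
print.boost_fit <- function(x, ...) {
  cat("boost_fit (", x$family, "): ", x$mstop, " iterations, ",
      length(unique(x$selection_path)), " distinct terms selected\n",
      "offset ", format(x$offset, digits = 4),
      "; risk ", format(x$risk_path[1], digits = 6), " -> ",
      format(x$risk_path[length(x$risk_path)], digits = 6), "\n", sep = "")
  invisible(x)
}

#' @export
fitted.boost_fit <- function(object, ...) object$fitted

#' @export
coef.boost_fit <- function(object, ...) object$aggregated

#' Predict from a boosting fit
#'
#' @param object a `boost_fit`.
#' @param newdata data frame to be mapped through the training design, or a
#'   pre-built numeric matrix aligned with it; `NULL` returns training-row
#'   predictions.
#' @param type "link" (offset + X beta) or "response" (inverse-logit thereof;
#'   identical to link for the Gaussian test mode).
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.boost_fit <- function(object, newdata = NULL,
                              type = c("link", "response"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    eta <- object$fitted
  } else {
    X <- if (is.matrix(newdata)) newdata
         else apply_design(object$design, newdata)
    if (ncol(X) != length(object$aggregated))
      stop("newdata has ", ncol(X), " design columns; fit expects ",
           length(object$aggregated))
    eta <- object$offset + drop(X %*% object$aggregated)
  }
  if (type == "response" && object$family == "binomial") stats::plogis(eta)
  else eta
}

#' @export
residuals.boost_fit <- function(object, ...) {
  negative_gradient(object$y, object$fitted, object$family)
}
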