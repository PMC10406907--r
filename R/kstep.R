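# K-step boosting: run the generic algorithm K times in sequence, each stage
# with its own base-learner set and stopping iteration, initializing stage k
# at stage k-1's fitted function (equivalently, resuming from its final
# pseudo-residual state). Stage ordering encodes a hierarchy: offering only
# main effects first and interactions second prioritizes simple explanations
# and removes the selection bias toward the O(p^2) interaction learners that a
# parallel (all-learners-at-once) fit suffers in the p > n regime.

#' One stage of a K-step configuration
#'
#' @param learners list of [ridge_learner()] objects for this stage.
#' @param mstop integer iteration count, or `"cv"` to select it by
#'   cross-validation at fitting time.
#' @param folds,cv_max,seed CV controls used when `mstop = "cv"`.
#' @return a `kstep_stage` list, to be passed to [kstep_boost()].
#' @export
kstep_stage <- function(learners, mstop = "cv", folds = 10, cv_max = 1000,
                        seed = NULL) {
  stopifnot(length(learners) >= 1)
  structure(list(learners = learners, mstop = mstop, folds = folds,
                 cv_max = cv_max, seed = seed), class = "kstep_stage")
}

# Fold-honest CV curve for stage k: within every training partition the
# earlier stages are replayed (refit at their already-chosen mstops) before
# the stage-k path is grown, so the out-of-fold risk never sees a fit trained
# on the held-out rows. Returns the fold-mean risk over m = 0..cv_max.
kstep_cv_curve <- function(design, y, prior, learners_k, eta, folds, cv_max,
                           seed, family, offset) {
  X <- design$values
  lab <- make_folds(y, folds, seed, stratify = (family == "binomial"))
  curves <- matrix(NA_real_, folds, cv_max + 1L)
  for (fold in seq_len(folds)) {
    tr <- which(lab != fold); te <- which(lab == fold)
    if (family == "binomial" && length(unique(y[tr])) < 2L)
      stop("training fold ", fold, " lost a class; use fewer folds")
    f_tr <- rep(init_offset(y[tr], family, offset), length(tr))
    f_te <- rep(f_tr[1L], length(te))
    for (pj in prior) {
      res <- boost_engine(X[tr, , drop = FALSE], y[tr], pj$learners, eta,
                          pj$mstop, f_tr, family,
                          Xv = X[te, , drop = FALSE], yv = y[te],
                          fv0 = f_te)
      f_tr <- res$f
      f_te <- f_te + drop(X[te, , drop = FALSE] %*% res$aggregated)
    }
    res <- boost_engine(X[tr, , drop = FALSE], y[tr], learners_k, eta,
                        cv_max, f_tr, family, Xv = X[te, , drop = FALSE],
                        yv = y[te], fv0 = f_te)
    curves[fold, ] <- res$valid_path
  }
  colMeans(curves)
}

#' K-step (two-step) boosting
#'
#' Runs [boost()] for stage 1, then restarts the algorithm for each later
#' stage from the current fitted function, restricting selection to that
#' stage's learner set. With one stage this is identical to a plain [boost()]
#' run; with a later stage stopped at 0 iterations the model is unchanged by
#' that stage. When a stage's `mstop` is `"cv"`, its stopping iteration is
#' chosen by fold-honest cross-validation: earlier stages are refit inside
#' every training partition (at their final iteration counts) before the
#' stage's own path is evaluated out of fold.
#'
#' @inheritParams boost
#' @param stages list of [kstep_stage()] objects (K >= 1).
#' @return object of class `kstep_fit`: the list of per-stage `boost_fit`s
#'   plus combined aggregated coefficients, a concatenated risk path and the
#'   final fitted values. Supports `predict`, `coef`, `fitted`.
#' @export
kstep_boost <- function(design, y, stages, eta = 0.1,
                        offset = c("logit-mean", "zero"),
                        family = c("binomial", "gaussian")) {
  family <- match.arg(family)
  offset <- match.arg(offset)
  stopifnot(inherits(design, "boost_design"), length(stages) >= 1)
  if (family == "binomial") y <- check_binary_outcome(y)
  f0 <- init_offset(y, family, offset)
  f_cur <- rep(f0, length(y))
  fits <- vector("list", length(stages))
  prior <- list()
  for (k in seq_along(stages)) {
    st <- stages[[k]]
    mstop <- st$mstop
    if (identical(mstop, "cv")) {
      curve <- kstep_cv_curve(design, y, prior, st$learners, eta, st$folds,
                              st$cv_max, st$seed, family, offset)
      mstop <- which.min(curve) - 1L
    }
    res <- boost_engine(design$values, y, st$learners, eta, mstop, f_cur,
                        family)
    fit <- new_boost_fit(res, design, st$learners, y, eta,
                         if (k == 1L) f0 else 0, family,
                         step_label = k)
    if (k > 1L) {
      # stage fits after the first report only their own contribution;
      # reconstruct their absolute risk path from the running fit
      fit$fitted <- res$f
    }
    fits[[k]] <- fit
    f_cur <- res$f
    prior[[k]] <- list(learners = st$learners, mstop = mstop)
  }
  aggregated <- Reduce(`+`, lapply(fits, function(f) f$aggregated))
  risk_path <- fits[[1L]]$risk_path
  for (k in seq_along(fits)[-1L])
    risk_path <- c(risk_path, fits[[k]]$risk_path[-1L])
  structure(list(stages = fits, offset = f0, aggregated = aggregated,
                 risk_path = risk_path, fitted = f_cur, y = y, eta = eta,
                 family = family, design = design),
            class = "kstep_fit")
}

#' @export
print.kstep_fit <- function(x, ...) {
  cat("kstep_fit (", x$family, "): ", length(x$stages), " stages, mstop = ",
      paste(vapply(x$stages, `[[`, 0L, "mstop"), collapse = " + "),
      "\nrisk ", format(x$risk_path[1], digits = 6), " -> ",
      format(x$risk_path[length(x$risk_path)], digits = 6), "\n", sep = "")
  invisible(x)
}

#' @export
coef.kstep_fit <- function(object, ...) object$aggregated

#' @export
fitted.kstep_fit <- function(object, ...) object$fitted

#' @rdname predict.boost_fit
#' @export
predict.kstep_fit <- function(object, newdata = NULL,
                              type = c("link", "response"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    eta <- object$fitted
  } else {
    X <- if (is.matrix(newdata)) newdata
         else apply_design(object$design, newdata)
    eta <- object$offset + drop(X %*% object$aggregated)
  }
  if (type == "response" && object$family == "binomial") stats::plogis(eta)
  else eta
}

#' @export
residuals.kstep_fit <- function(object, ...) {
  negative_gradient(object$y, object$fitted, object$family)
}
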