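#' Fit an interpretable boosting model
#'
#' The front end tying the package together: builds the centered
#' block-structured design from the data and dictionary, constructs the
#' requested model configuration, selects the stopping iteration by 10-fold
#' cross-validation (unless given), and fits by component-wise functional
#' gradient descent. Four configurations are available:
#'
#' * `"mb"` — component-wise boosting with one df-1 ridge learner per
#'   variable;
#' * `"mb-int"` — the mb learners plus one df-1 learner per
#'   moderator-by-variable interaction term, offered in parallel;
#' * `"sgb"` — sparse-group boosting with mixing parameter `alpha`;
#' * `"2boost"` — two-step boosting: main effects first, interactions second.
#'
#' @param data data frame with the dictionary variables and the outcome.
#' @param dictionary a `boost_dictionary` (or data frame coercible via
#'   [as_dictionary()]).
#' @param outcome name of the 0/1 outcome column in `data`.
#' @param model one of `"mb"`, `"mb-int"`, `"sgb"`, `"2boost"`.
#' @param eta learning rate in (0,1].
#' @param alpha sparse-group mixing parameter in \[0,1\] (sgb only).
#' @param mstop `"cv"` (default) or an integer iteration count; for
#'   `"2boost"` optionally a length-2 vector for the two stages.
#' @param folds,cv_max cross-validation controls.
#' @param seed integer seed for fold assignment.
#' @param offset `"logit-mean"` (default) or `"zero"`.
#' @param moderator_pairs include moderator-moderator interaction pairs.
#' @return an object of class `ridgeboost` with `print`, `summary`, `coef`,
#'   `predict`, `fitted`, `residuals`, `simulate` and `plot` methods.
#' @examples
#' sim <- simulate_survey(survey_spec(scale = 0.15, seed = 42))
#' fit <- ridgeboost(sim$data, sim$dictionary, "outcome", model = "mb",
#'                   mstop = 25)
#' print(fit)
#' head(variable_importance(fit))
#' @export
ridgeboost <- function(data, dictionary, outcome,
                       model = c("mb", "mb-int", "sgb", "2boost"),
                       eta = 0.1, alpha = 0.5, mstop = "cv", folds = 10,
                       cv_max = 1000, seed = 1,
                       offset = c("logit-mean", "zero"),
                       moderator_pairs = TRUE) {
  model <- match.arg(model)
  offset <- match.arg(offset)
  dictionary <- as_dictionary(dictionary)
  if (!outcome %in% names(data))
    stop("outcome column '", outcome, "' not found in data")
  y <- check_binary_outcome(data[[outcome]])
  design <- build_design(data, dictionary)
  cv_used <- identical(mstop, "cv") ||
    (model == "2boost" && any(mstop == "cv"))
  if (model %in% c("mb", "sgb")) {
    learners <- if (model == "mb") make_mb(design)
                else make_sgb(design, alpha)
    if (identical(mstop, "cv"))
      mstop <- as.integer(cv_mstop(design, y, learners, eta, folds, cv_max,
                                   seed, offset))
    fit <- boost(design, y, learners, eta, mstop, offset)
    mstops <- fit$mstop
  } else if (model == "mb-int") {
    cfg <- make_mb_int(design, build_interactions(design, moderator_pairs))
    if (identical(mstop, "cv"))
      mstop <- as.integer(cv_mstop(cfg$design, y, cfg$learners, eta, folds,
                                   cv_max, seed, offset))
    fit <- boost(cfg$design, y, cfg$learners, eta, mstop, offset)
    design <- cfg$design
    mstops <- fit$mstop
  } else {
    if (identical(mstop, "cv")) mstop <- c("cv", "cv")
    cfg <- make_2boost(design, build_interactions(design, moderator_pairs),
                       mstop1 = if (identical(mstop[1], "cv")) "cv"
                                else as.integer(mstop[1]),
                       mstop2 = if (identical(mstop[2], "cv")) "cv"
                                else as.integer(mstop[2]),
                       folds = folds, cv_max = cv_max, seed = seed)
    fit <- kstep_boost(cfg$design, y, cfg$stages, eta, offset)
    design <- cfg$design
    mstops <- vapply(fit$stages, `[[`, 0L, "mstop")
  }
  structure(list(fit = fit, model = model, design = design, y = y,
                 outcome = outcome, eta = eta, alpha = alpha,
                 mstop = mstops, cv = cv_used, seed = seed,
                 call = match.call()),
            class = "ridgeboost")
}

#' @export
print.ridgeboost <- function(x, ...) {
  cat("ridgeboost model '", x$model, "' on outcome '", x$outcome, "'\n",
      "n = ", length(x$y), ", design columns = ", x$design$p,
      ", mstop = ", paste(x$mstop, collapse = " + "),
      if (x$cv) " (CV)", ", eta = ", x$eta, "\n", sep = "")
  sel <- selected_terms(x)
  cat("terms selected: ", length(sel),
      if (length(sel)) paste0(" (", paste(utils::head(sel, 5),
                                          collapse = ", "),
                              if (length(sel) > 5) ", ...", ")"),
      "\n", sep = "")
  invisible(x)
}

# Distinct term ids in selection order (all stages for a K-step fit).
selected_terms <- function(object) {
  fit <- object$fit
  paths <- if (inherits(fit, "kstep_fit"))
    unlist(lapply(fit$stages, `[[`, "selection_path"))
  else fit$selection_path
  unique(paths)
}

# Distinct interaction term ids selected by a fit.
selected_interaction_terms <- function(object) {
  fit <- object$fit
  pieces <- if (inherits(fit, "kstep_fit")) fit$stages else list(fit)
  out <- character(0)
  for (f in pieces) {
    kinds <- vapply(f$learners, `[[`, "", "kind")
    ids <- vapply(f$learners, `[[`, "", "id")
    out <- c(out, intersect(unique(f$selection_path),
                            ids[kinds == "interaction"]))
  }
  unique(out)
}

#' @export
coef.ridgeboost <- function(object, ...) stats::coef(object$fit)

#' @export
fitted.ridgeboost <- function(object, ...) stats::fitted(object$fit)

#' @export
residuals.ridgeboost <- function(object, ...) stats::residuals(object$fit)

#' @rdname predict.boost_fit
#' @export
predict.ridgeboost <- function(object, newdata = NULL,
                               type = c("link", "response"), ...) {
  stats::predict(object$fit, newdata = newdata, type = match.arg(type))
}

#' Simulate outcomes from a fitted model
#'
#' Draws Bernoulli outcomes from the fitted response probabilities, the
#' parametric-bootstrap primitive for a boosted logistic model.
#'
#' @param object a `ridgeboost` fit.
#' @param nsim number of simulated outcome vectors.
#' @param seed optional seed (caller's RNG state restored).
#' @param ... unused.
#' @return data frame with `nsim` columns of 0/1 outcomes.
#' @export
simulate.ridgeboost <- function(object, nsim = 1, seed = NULL, ...) {
  p <- stats::predict(object, type = "response")
  with_seed(seed, {
    out <- as.data.frame(replicate(nsim, stats::rbinom(length(p), 1, p)))
    names(out) <- paste0("sim_", seq_len(nsim))
    out
  })
}

#' @export
summary.ridgeboost <- function(object, top = 10, ...) {
  imp <- variable_importance(object$fit)
  eff <- aggregated_effects(object$fit)
  eff <- eff[eff$coefficient != 0, , drop = FALSE]
  structure(list(object = object, importance = imp, effects = eff,
                 top = top,
                 n_interactions = length(selected_interaction_terms(object))),
            class = "summary.ridgeboost")
}

#' @export
print.summary.ridgeboost <- function(x, ...) {
  print(x$object)
  if (x$object$model %in% c("mb-int", "2boost"))
    cat("interaction terms selected: ", x$n_interactions, "\n", sep = "")
  cat("\nVariable importance (top ", min(x$top, nrow(x$importance)),
      "):\n", sep = "")
  print(utils::head(as.data.frame(x$importance), x$top), digits = 3)
  cat("\nNonzero aggregated effects (odds ratios):\n")
  print(utils::head(x$effects[order(-abs(x$effects$coefficient)), ], x$top),
        digits = 3)
  invisible(x)
}

#' Plot a boosting fit
#'
#' `type = "risk"` draws the in-sample negative log-likelihood over the
#' boosting iterations; `type = "importance"` a horizontal bar chart of the
#' variable-importance percentages (display options `min_percent` and
#' `max_terms` mirror the usual reporting filters).
#'
#' @param x a `ridgeboost` fit.
#' @param type "risk" or "importance".
#' @param min_percent,max_terms importance-display filters.
#' @param ... passed to the underlying plot call.
#' @export
plot.ridgeboost <- function(x, type = c("risk", "importance"),
                            min_percent = 1, max_terms = 15, ...) {
  type <- match.arg(type)
  if (type == "risk") {
    rp <- x$fit$risk_path
    graphics::plot(seq_along(rp) - 1, rp, type = "l", xlab = "iteration",
                   ylab = "negative log-likelihood",
                   main = paste("risk path:", x$model), ...)
  } else {
    imp <- variable_importance(x$fit)
    imp <- imp[imp$percent >= min_percent, , drop = FALSE]
    imp <- utils::head(imp, max_terms)
    if (!nrow(imp)) {
      warning("no terms pass the display filter")
      return(invisible(x))
    }
    old <- graphics::par(mar = c(4, 12, 2, 1))
    on.exit(graphics::par(old))
    graphics::barplot(rev(imp$percent), names.arg = rev(imp$term),
                      horiz = TRUE, las = 1, xlab = "% risk reduction",
                      main = paste("variable importance:", x$model), ...)
  }
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", xlab = "false positive rate",
                 ylab = "true positive rate",
                 main = sprintf("ROC (AUC = %.3f)", attr(x, "auc")), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}
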