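# End-to-end orchestration: split, fit, evaluate, write artifacts. These are
# the functions behind the command-line wrapper in inst/cli/.

#' Run one model end to end and write its artifact bundle
#'
#' Splits the data (stratified 70/30 by default), fits the requested model on
#' the training rows with CV-selected stopping, evaluates the test AUC, and
#' writes `metrics.csv`, `coefficients.csv`, `importance.csv`, `roc.csv` and
#' a JSON run manifest recording every seed, lambda and mstop to `out_dir`.
#'
#' @inheritParams ridgeboost
#' @param out_dir output directory (created); `NULL` skips writing.
#' @param split_fraction training fraction (default 0.7).
#' @param split_seed seed for the train/test split.
#' @return invisibly, a list with the fitted `ridgeboost` object, the split,
#'   the test `auc`, the importance and effects tables, and the file paths.
#' @export
run_fit <- function(data, dictionary, outcome,
                    model = c("mb", "mb-int", "sgb", "2boost"),
                    out_dir = NULL, split_fraction = 0.7, split_seed = 1,
                    eta = 0.1, alpha = 0.5, mstop = "cv", folds = 10,
                    cv_max = 1000, seed = 1) {
  model <- match.arg(model)
  dictionary <- as_dictionary(dictionary)
  y <- check_binary_outcome(data[[outcome]])
  plan <- split_data(y, split_fraction, split_seed)
  train <- data[plan$train, , drop = FALSE]
  test <- data[plan$test, , drop = FALSE]
  fit <- ridgeboost(train, dictionary, outcome, model, eta = eta,
                    alpha = alpha, mstop = mstop, folds = folds,
                    cv_max = cv_max, seed = seed)
  scores <- predict(fit, newdata = test, type = "response")
  test_auc <- auc(scores, y[plan$test])
  roc <- roc_curve(scores, y[plan$test])
  imp <- variable_importance(fit$fit)
  eff <- aggregated_effects(fit$fit)
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    lam <- unlist(lapply(all_learners(fit), function(l)
      stats::setNames(l$lambda, l$id)))
    dfs <- unlist(lapply(all_learners(fit), function(l)
      stats::setNames(l$df, l$id)))
    paths <- c(metrics = file.path(out_dir, "metrics.csv"),
               coefficients = file.path(out_dir, "coefficients.csv"),
               importance = file.path(out_dir, "importance.csv"),
               roc = file.path(out_dir, "roc.csv"),
               manifest = file.path(out_dir, "manifest.json"))
    utils::write.csv(data.frame(model = model, outcome = outcome,
                                auc = test_auc,
                                mstop = paste(fit$mstop, collapse = "+"),
                                n_train = length(plan$train),
                                n_test = length(plan$test)),
                     paths["metrics"], row.names = FALSE)
    eff_out <- eff
    eff_out$lambda <- lam[eff_out$term]
    eff_out$df <- dfs[eff_out$term]
    utils::write.csv(eff_out, paths["coefficients"], row.names = FALSE)
    utils::write.csv(as.data.frame(imp), paths["importance"],
                     row.names = FALSE)
    utils::write.csv(as.data.frame(roc), paths["roc"], row.names = FALSE)
    jsonlite::write_json(
      list(model = model, outcome = outcome, eta = eta, alpha = alpha,
           mstop = fit$mstop, cv = fit$cv, cv_seed = seed,
           split_fraction = split_fraction, split_seed = split_seed,
           n_train = length(plan$train), n_test = length(plan$test),
           selection_path = selection_paths(fit),
           package_version = as.character(utils::packageVersion("ridgeboost"))),
      paths["manifest"], auto_unbox = TRUE, digits = NA)
  }
  invisible(list(fit = fit, split = plan, auc = test_auc, roc = roc,
                 importance = imp, effects = eff, paths = paths))
}

all_learners <- function(object) {
  f <- object$fit
  if (inherits(f, "kstep_fit")) unlist(lapply(f$stages, `[[`, "learners"),
                                      recursive = FALSE)
  else f$learners
}

selection_paths <- function(object) {
  f <- object$fit
  if (inherits(f, "kstep_fit"))
    lapply(f$stages, `[[`, "selection_path")
  else list(f$selection_path)
}

#' Compare models across outcomes
#'
#' Fits every (model, outcome) combination with [run_fit()] and tabulates the
#' test AUC, the number of distinct interaction terms selected, and the
#' percentage of offered interaction terms selected (1-sparsity, denominator
#' = interaction terms offered to the model; 0 for models without interaction
#' learners). Per-model mean AUCs across outcomes are attached as attribute
#' `"mean_auc"`.
#'
#' @inheritParams run_fit
#' @param models character vector of model names.
#' @param outcomes character vector of outcome column names.
#' @return data frame with one row per (model, outcome).
#' @export
run_compare <- function(data, dictionary, outcomes,
                        models = c("mb", "mb-int", "sgb", "2boost"),
                        split_fraction = 0.7, split_seed = 1, eta = 0.1,
                        alpha = 0.5, mstop = "cv", folds = 10, cv_max = 1000,
                        seed = 1) {
  rows <- list()
  for (model in models) {
    for (outcome in outcomes) {
      res <- run_fit(data, dictionary, outcome, model,
                     split_fraction = split_fraction,
                     split_seed = split_seed, eta = eta, alpha = alpha,
                     mstop = mstop, folds = folds, cv_max = cv_max,
                     seed = seed)
      n_int <- length(selected_interaction_terms(res$fit))
      offered <- sum(vapply(all_learners(res$fit), function(l)
        l$kind == "interaction", TRUE))
      rows[[length(rows) + 1L]] <- data.frame(
        model = model, outcome = outcome, auc = res$auc,
        n_interactions = n_int,
        interactions_offered = offered,
        one_minus_sparsity_pct = if (offered > 0)
          round(100 * n_int / offered, 2) else 0,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  mean_auc <- tapply(out$auc, out$model, mean)
  attr(out, "mean_auc") <- mean_auc[unique(out$model)]
  out
}
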