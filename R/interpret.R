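# Interpretation of fitted boosting models: likelihood-reduction variable
# importance, aggregated coefficients / odds ratios, partial-effect profiles,
# and standalone univariate interaction probability profiles.

#' Likelihood-reduction variable importance
#'
#' Credits the drop in in-sample negative log-likelihood at each boosting
#' iteration to the base-learner selected there, aggregates per term, and
#' reports each term's share of the total reduction. The absolute reductions
#' sum exactly to `risk_path[1] - risk_path[end]`. For a K-step fit the
#' stages are concatenated into one table with a `step` column and percentages
#' taken relative to the combined reduction.
#'
#' @param fit a `boost_fit` or `kstep_fit`.
#' @return data frame of class `boost_importance` with columns `term`, `kind`,
#'   `step`, `reduction`, `percent`, ordered by decreasing reduction. Zero
#'   total reduction reports zero percentages with a warning.
#' @export
variable_importance <- function(fit) {
  pieces <- if (inherits(fit, "kstep_fit")) fit$stages else list(fit)
  rows <- list()
  for (k in seq_along(pieces)) {
    f <- pieces[[k]]
    if (f$mstop == 0L) next
    red <- -diff(f$risk_path)
    kinds <- vapply(f$learners, `[[`, "", "kind")
    for (term in unique(f$selection_path)) {
      sel <- f$selection_path == term
      rows[[length(rows) + 1L]] <- data.frame(
        term = term,
        kind = kinds[[match(term, vapply(f$learners, `[[`, "", "id"))]],
        step = f$step_label %||% 1L,
        reduction = sum(red[sel]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    out <- data.frame(term = character(0), kind = character(0),
                      step = integer(0), reduction = numeric(0),
                      percent = numeric(0))
    class(out) <- c("boost_importance", class(out))
    return(out)
  }
  out <- do.call(rbind, rows)
  total <- sum(out$reduction)
  if (total <= 0) {
    warning("total risk reduction is zero; percentages set to 0")
    out$percent <- 0
  } else {
    out$percent <- 100 * out$reduction / total
  }
  out <- out[order(-out$reduction), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("boost_importance", class(out))
  out
}

#' Aggregated coefficients and odds ratios per base-learner
#'
#' Sums the learning-rate-scaled coefficient increments over all iterations in
#' which a term was selected, per design column, and exponentiates into odds
#' ratios (contrast against the reference category for dummy columns). Terms
#' never selected have coefficient 0 and odds ratio 1.
#'
#' @param fit a `boost_fit` or `kstep_fit`.
#' @return data frame with columns `term`, `kind`, `column`, `coefficient`,
#'   `odds_ratio`.
#' @export
aggregated_effects <- function(fit) {
  pieces <- if (inherits(fit, "kstep_fit")) fit$stages else list(fit)
  design <- pieces[[1L]]$design
  agg <- if (inherits(fit, "kstep_fit")) fit$aggregated else fit$aggregated
  learner_of_block <- list()
  for (f in pieces)
    for (l in f$learners) learner_of_block[[l$id]] <- l$kind
  rows <- lapply(design$blocks, function(b) {
    data.frame(term = b$id,
               kind = learner_of_block[[b$id]] %||% b$kind,
               column = colnames(design$values)[b$cols],
               coefficient = unname(agg[b$cols]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out$odds_ratio <- exp(out$coefficient)
  out
}

#' Partial effect of one term
#'
#' Predicted response-scale probabilities as the chosen term's category varies
#' while every other term is held at its average training contribution. Since
#' all design columns are centered, each term's mean training contribution on
#' the link scale is zero, so the baseline is the model offset; the term's own
#' contribution is evaluated at the (uncentered) dummy codes of each category
#' minus the stored column means.
#'
#' @param fit a `boost_fit` or `kstep_fit`.
#' @param term a main-effect or interaction term id present in the fit's
#'   design.
#' @param grid for a continuous variable, the numeric values to profile
#'   (default: quartiles of nothing is available, so required); ignored for
#'   categorical terms, whose declared categories are used.
#' @return data frame with the category combination and columns `link`,
#'   `probability`.
#' @export
partial_effect <- function(fit, term, grid = NULL) {
  design <- fit$design
  b <- design$blocks[[term]]
  if (is.null(b)) stop("term '", term, "' not in the fitted design")
  agg <- if (inherits(fit, "kstep_fit")) fit$aggregated else fit$aggregated
  dict <- design$dictionary
  cat_grid <- function(v) {
    i <- match(v, dict$variable)
    if (dict$type[i] == "continuous") {
      if (is.null(grid)) stop("continuous term '", v, "' needs a `grid`")
      grid
    } else dict$categories[[i]]
  }
  vars <- b$vars
  combos <- expand.grid(lapply(vars, cat_grid), stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
  names(combos) <- vars
  # raw block values for each combo: dummy codes (or numeric value), products
  # for interaction blocks, then centered with the training means
  raw_for <- function(v, val) {
    i <- match(v, dict$variable)
    if (dict$type[i] == "continuous") return(as.numeric(val))
    lev <- dict$categories[[i]][-1]
    as.numeric(lev == val)
  }
  link <- vapply(seq_len(nrow(combos)), function(r) {
    pieces <- lapply(vars, function(v) raw_for(v, combos[r, v]))
    raw <- if (length(pieces) == 1L) pieces[[1L]]
           else as.vector(outer(pieces[[1L]], pieces[[2L]]))
    centered <- raw - design$column_means[b$cols]
    fit$offset + sum(centered * agg[b$cols])
  }, 0)
  out <- combos
  out$link <- link
  out$probability <- if (fit$family == "binomial") stats::plogis(link)
                     else link
  out
}

#' Univariate interaction probability profile
#'
#' Fits a standalone classical logistic regression with both main effects and
#' their interaction (saturated for binary-by-binary) and returns the fitted
#' outcome probability for every joint category, optionally repeated within
#' strata. This is the descriptive companion to the boosted interaction
#' screen: one interaction term at a time, on raw data.
#'
#' @param data data frame with the two variables (and the stratum variable).
#' @param y binary outcome vector (0/1), length `nrow(data)`.
#' @param moderator,partner names of two categorical/binary variables.
#' @param dictionary optional `boost_dictionary` supplying declared category
#'   orders; defaults to the observed levels.
#' @param stratify_by optional name of a stratification variable; the model is
#'   then fit separately per stratum, plus once on the whole data.
#' @return data frame with columns `stratum`, the two variables, `n` (cell
#'   count) and `probability` (NA, flagged in `empty_cell`, where a joint cell
#'   is empty in the analyzed stratum).
#' @export
interaction_profile <- function(data, y, moderator, partner,
                                dictionary = NULL, stratify_by = NULL) {
  y <- check_binary_outcome(y)
  lev_of <- function(v) {
    if (!is.null(dictionary)) {
      i <- match(v, dictionary$variable)
      if (!is.na(i) && dictionary$type[i] != "continuous")
        return(dictionary$categories[[i]])
    }
    sort(unique(as.character(data[[v]])))
  }
  mlev <- lev_of(moderator); plev <- lev_of(partner)
  fac_m <- factor(as.character(data[[moderator]]), levels = mlev)
  fac_p <- factor(as.character(data[[partner]]), levels = plev)
  strata <- list(all = rep(TRUE, nrow(data)))
  if (!is.null(stratify_by)) {
    for (s in sort(unique(as.character(data[[stratify_by]]))))
      strata[[s]] <- as.character(data[[stratify_by]]) == s
  }
  out <- list()
  for (s in names(strata)) {
    keep <- strata[[s]]
    df <- data.frame(y = y[keep], m = fac_m[keep], p = fac_p[keep])
    grid <- expand.grid(m = factor(mlev, levels = mlev),
                        p = factor(plev, levels = plev),
                        KEEP.OUT.ATTRS = FALSE)
    counts <- vapply(seq_len(nrow(grid)), function(i)
      sum(df$m == grid$m[i] & df$p == grid$p[i]), 0L)
    prob <- rep(NA_real_, nrow(grid))
    ok <- counts > 0L
    if (all(ok)) {
      mod <- stats::glm(y ~ m * p, family = stats::binomial(), data = df)
      prob <- as.numeric(stats::predict(mod, newdata = grid,
                                        type = "response"))
    } else if (any(counts > 0L)) {
      # empty joint cells: fit on the observed cells only and flag the rest
      mod <- stats::glm(y ~ m * p, family = stats::binomial(), data = df)
      prob[ok] <- as.numeric(stats::predict(mod, newdata = grid[ok, ],
                                            type = "response"))
    }
    res <- data.frame(stratum = s, grid$m, grid$p, n = counts,
                      probability = prob, empty_cell = counts == 0L,
                      stringsAsFactors = FALSE)
    names(res)[2:3] <- c(moderator, partner)
    out[[s]] <- res
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
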