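# Synthetic survey-style data with planted effects.
#
# Emulates the statistical shape of a farm-household vulnerability survey:
# ~800 respondents, ~75 mostly binary variables organized in named asset
# groups, a handful of multi-category variables (a 4-region geography, a
# 3-level social-norms item), 22 flagged potential moderators, and a binary
# outcome generated from a logistic model with chosen main and interaction
# coefficients. Covariates are drawn independently by default; the truth
# record keeps the exact linear predictor per row so estimators can be
# checked against the generating model.

#' Construct a synthetic-data specification
#'
#' @param n number of observations.
#' @param variables data frame with columns `variable`, `type`, `categories`
#'   (list-column), `probs` (list-column of category probabilities, each
#'   summing to 1; ignored for continuous variables), `group`,
#'   `is_moderator`.
#' @param intercept intercept of the generating logistic model.
#' @param main_effects named list: variable -> coefficient vector over its
#'   non-reference categories (length 1 for binary, c-1 for categorical).
#' @param interaction_effects named list: `"moderator:partner"` -> coefficient
#'   vector over the product block (moderator dummy varying fastest).
#' @param seed integer seed used by [simulate_survey()].
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n, variables, intercept = 0,
                           main_effects = list(),
                           interaction_effects = list(), seed = 1) {
  stopifnot(is.data.frame(variables), n >= 1)
  for (i in seq_len(nrow(variables))) {
    if (variables$type[i] == "continuous") next
    pr <- variables$probs[[i]]
    if (length(pr) != length(variables$categories[[i]]) ||
        any(pr < 0) || abs(sum(pr) - 1) > 1e-8)
      stop("invalid category probabilities for variable '",
           variables$variable[i], "'")
  }
  for (v in names(main_effects))
    if (!v %in% variables$variable)
      stop("main effect on undeclared variable '", v, "'")
  for (key in names(interaction_effects)) {
    pair <- strsplit(key, ":", fixed = TRUE)[[1]]
    if (length(pair) != 2 || !all(pair %in% variables$variable))
      stop("interaction effect on undeclared pair '", key, "'")
  }
  structure(list(n = as.integer(n), variables = variables,
                 intercept = intercept, main_effects = main_effects,
                 interaction_effects = interaction_effects,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Raw dummy codes for one variable's drawn values (reference = first
# category), matching the design-matrix coding.
dummy_codes <- function(values, categories) {
  lev <- categories[-1]
  vapply(lev, function(cat) as.numeric(values == cat),
         numeric(length(values)))
}

# Linear predictor of the generating model on drawn covariates.
truth_linear_predictor <- function(spec, data) {
  lp <- rep(spec$intercept, nrow(data))
  vars <- spec$variables
  dmy <- function(v) {
    i <- match(v, vars$variable)
    if (vars$type[i] == "continuous")
      matrix(as.numeric(data[[v]]), ncol = 1)
    else
      matrix(dummy_codes(data[[v]], vars$categories[[i]]), nrow = nrow(data))
  }
  for (v in names(spec$main_effects))
    lp <- lp + drop(dmy(v) %*% spec$main_effects[[v]])
  for (key in names(spec$interaction_effects)) {
    pair <- strsplit(key, ":", fixed = TRUE)[[1]]
    M <- dmy(pair[1]); P <- dmy(pair[2])
    prod <- M[, rep(seq_len(ncol(M)), times = ncol(P)), drop = FALSE] *
      P[, rep(seq_len(ncol(P)), each = ncol(M)), drop = FALSE]
    lp <- lp + drop(prod %*% spec$interaction_effects[[key]])
  }
  lp
}

#' Generate a synthetic survey dataset
#'
#' Draws every covariate independently from its declared category
#' probabilities (standard normal for continuous variables), computes the
#' generating linear predictor, and draws the outcome
#' Bernoulli(plogis(linear predictor)). The same spec (including its seed)
#' reproduces the dataset exactly.
#'
#' @param spec a [synthetic_spec()].
#' @param outcome_name name of the outcome column appended to the data
#'   (default "outcome").
#' @return list with `data` (data frame of covariates plus the 0/1 outcome),
#'   `dictionary` (a `boost_dictionary`), and `truth` (the spec plus the
#'   per-row linear predictor and event probability).
#' @export
simulate_survey <- function(spec, outcome_name = "outcome") {
  stopifnot(inherits(spec, "synthetic_spec"))
  vars <- spec$variables
  with_seed(spec$seed, {
    data <- as.data.frame(lapply(seq_len(nrow(vars)), function(i) {
      if (vars$type[i] == "continuous") stats::rnorm(spec$n)
      else sample(vars$categories[[i]], spec$n, replace = TRUE,
                  prob = vars$probs[[i]])
    }), stringsAsFactors = FALSE)
    names(data) <- vars$variable
    lp <- truth_linear_predictor(spec, data)
    y <- stats::rbinom(spec$n, 1, stats::plogis(lp))
  })
  data[[outcome_name]] <- y
  dictionary <- as_dictionary(data.frame(
    variable = vars$variable, type = vars$type,
    categories = I(vars$categories), group = vars$group,
    is_moderator = vars$is_moderator, stringsAsFactors = FALSE))
  list(data = data, dictionary = dictionary,
       truth = list(spec = spec, linear_predictor = lp,
                    probability = stats::plogis(lp)))
}

#' Write a simulated dataset to plain-text files
#'
#' @param sim result of [simulate_survey()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written: `data.csv`, `dictionary.csv`,
#'   `truth.json`.
#' @export
write_survey <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(data = file.path(dir, "data.csv"),
             dictionary = file.path(dir, "dictionary.csv"),
             truth = file.path(dir, "truth.json"))
  utils::write.csv(sim$data, paths["data"], row.names = FALSE, quote = TRUE)
  write_dictionary(sim$dictionary, paths["dictionary"])
  spec <- sim$truth$spec
  jsonlite::write_json(
    list(n = spec$n, intercept = spec$intercept, seed = spec$seed,
         main_effects = spec$main_effects,
         interaction_effects = spec$interaction_effects,
         linear_predictor = sim$truth$linear_predictor),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

# Full-scale variable table: 75 variables in 10 named groups, category
# probabilities chosen to mimic realistic farm-survey marginals, 22 moderators
# (flagged TRUE). Order within groups puts moderators and planted-effect
# variables first so scaled-down specs retain them.
survey_variable_table <- function() {
  bin <- function(name, p, group, mod = FALSE)
    data.frame(variable = name, type = "binary",
               categories = I(list(c("no", "yes"))),
               probs = I(list(c(1 - p, p))), group = group,
               is_moderator = mod, stringsAsFactors = FALSE)
  rows <- list(
    data.frame(variable = "region", type = "categorical",
               categories = I(list(c("central_chile", "central_tunisia",
                                     "northern_tunisia", "southern_chile"))),
               probs = I(list(c(200, 200, 201, 200) / 801)),
               group = "natural", is_moderator = TRUE,
               stringsAsFactors = FALSE),
    bin("increasing_temperature", 629 / 801, "climate_experience", TRUE),
    bin("decreasing_rain", 659 / 801, "climate_experience", TRUE),
    bin("increasing_drought", 671 / 801, "climate_experience", TRUE),
    bin("increasing_extreme_weather", 542 / 801, "climate_experience", TRUE),
    bin("agronomic_measures", 647 / 801, "biophysical", TRUE),
    bin("economic_measures", 464 / 801, "biophysical", TRUE),
    bin("well_irrigation", 231 / 801, "biophysical", TRUE),
    bin("technological_measures", 721 / 801, "biophysical", TRUE),
    bin("river_irrigation", 138 / 801, "biophysical"),
    bin("large_farm", 283 / 801, "biophysical"),
    bin("large_orchard", 318 / 801, "biophysical"),
    bin("multiple_varieties", 508 / 801, "biophysical"),
    bin("other_products", 571 / 801, "biophysical"),
    bin("drip_irrigation", 0.45, "biophysical"),
    bin("income_invested_gt80", 137 / 801, "economic", TRUE),
    bin("high_farm_debt", 96 / 801, "economic", TRUE),
    bin("high_adaptive_efficacy", 490 / 801, "economic", TRUE),
    bin("income_invested_lt40", 358 / 801, "economic"),
    bin("high_financial_wellbeing", 346 / 801, "economic"),
    bin("low_financial_wellbeing", 148 / 801, "economic"),
    bin("dependent_on_farm", 528 / 801, "economic"),
    bin("family_farm_engagement", 203 / 801, "economic"),
    bin("keep_tradition", 460 / 801, "goals", TRUE),
    bin("profitable_business", 320 / 801, "goals", TRUE),
    bin("work_independent", 635 / 801, "goals"),
    bin("good_living_environment", 466 / 801, "goals"),
    bin("expand_farm", 0.5, "goals"),
    bin("high_optimism", 446 / 801, "harm", TRUE),
    bin("climate_harmful", 258 / 801, "harm"),
    bin("high_certainty", 470 / 801, "harm"),
    bin("climate_threatens_farm", 629 / 801, "harm"),
    bin("risks_exceed_benefits", 648 / 801, "harm"),
    bin("climate_concern", 0.6, "harm"),
    bin("age_over_50", 438 / 801, "human", TRUE),
    bin("gender_female", 121 / 801, "human", TRUE),
    bin("formal_education", 459 / 801, "human", TRUE),
    bin("climate_acceptance", 676 / 801, "human"),
    bin("human_cause", 685 / 801, "human"),
    bin("climate_extremes", 755 / 801, "human"),
    bin("long_possession", 577 / 801, "human"),
    bin("prior_family_ownership", 399 / 801, "human"),
    bin("long_managing", 437 / 801, "human"),
    bin("large_household", 0.5, "human"),
    bin("use_tv", 415 / 801, "social", TRUE),
    bin("use_farm_associations", 97 / 801, "social", TRUE),
    bin("trust_tv", 329 / 801, "social", TRUE),
    bin("trust_industry", 215 / 801, "social", TRUE),
    bin("use_newspapers", 95 / 801, "social"),
    bin("use_farming_journals", 161 / 801, "social"),
    bin("use_radio", 219 / 801, "social"),
    bin("use_internet", 319 / 801, "social"),
    bin("use_extension_workers", 346 / 801, "social"),
    bin("use_government_workers", 166 / 801, "social"),
    bin("use_neighbours", 313 / 801, "social"),
    bin("use_industry", 192 / 801, "social"),
    bin("trust_newspapers", 174 / 801, "social"),
    bin("trust_farming_journals", 291 / 801, "social"),
    bin("trust_radio", 241 / 801, "social"),
    bin("trust_internet", 319 / 801, "social"),
    bin("trust_extension_workers", 433 / 801, "social"),
    bin("trust_government_workers", 268 / 801, "social"),
    bin("trust_neighbours", 319 / 801, "social"),
    bin("trust_farm_associations", 184 / 801, "social"),
    bin("trust_government_institutions", 312 / 801, "social"),
    bin("trust_other_farmers", 351 / 801, "social"),
    bin("trust_religion", 317 / 801, "social"),
    bin("trust_fate", 360 / 801, "social"),
    bin("crop_damage_near", 643 / 801, "spatial"),
    bin("crop_damage_country", 673 / 801, "spatial"),
    bin("climate_occurs", 592 / 801, "spatial"),
    bin("neighbours_adapting", 0.53, "spatial"),
    data.frame(variable = "adaptive_norms", type = "categorical",
               categories = I(list(c("low", "medium", "high"))),
               probs = I(list(c(424, 151, 226) / 801)),
               group = "norms", is_moderator = FALSE,
               stringsAsFactors = FALSE),
    bin("community_expectation", 0.5, "norms"),
    bin("social_pressure", 0.45, "norms")
  )
  do.call(rbind, c(rows, make.row.names = FALSE))
}

# Deterministic intercept calibration: bisect the intercept so that the
# expected outcome prevalence under the spec's covariate distribution matches
# `target`, using a fixed-seed Monte Carlo draw of the linear predictor.
calibrate_intercept <- function(variables, main_effects, interaction_effects,
                                target, draws = 20000) {
  base <- synthetic_spec(draws, variables, intercept = 0,
                         main_effects = main_effects,
                         interaction_effects = interaction_effects,
                         seed = 190748)
  lp0 <- with_seed(190748L, {
    data <- as.data.frame(lapply(seq_len(nrow(variables)), function(i) {
      if (variables$type[i] == "continuous") stats::rnorm(draws)
      else sample(variables$categories[[i]], draws, replace = TRUE,
                  prob = variables$probs[[i]])
    }), stringsAsFactors = FALSE)
    names(data) <- variables$variable
    truth_linear_predictor(base, data)
  })
  stats::uniroot(function(c0) mean(stats::plogis(c0 + lp0)) - target,
                 c(-20, 20), tol = 1e-8)$root
}

#' Survey-like synthetic-data specification
#'
#' The package's reference study conditions: at `scale = 1`, 801 observations
#' and 75 mostly binary variables in 10 named groups (climate experience,
#' natural, social, human, biophysical, economic, goals, harm, spatial,
#' norms), one 4-category geography variable and one 3-category norms
#' variable, and 22 flagged moderators — yielding 1397 variable-level
#' interaction terms whose expanded columns exceed n (the p > n interaction
#' regime). Default planted effects are region main effects, one economic
#' main effect and two region-by-goal interactions; the intercept is
#' calibrated (deterministically) so the expected outcome prevalence is
#' 358/801.
#'
#' @param scale size multiplier in (0, 1\]: observation count and per-group
#'   variable counts shrink proportionally (moderators and planted-effect
#'   variables are listed first within groups, so they are retained longest).
#' @param seed seed stored in the spec.
#' @param main_effects,interaction_effects override the default planted
#'   effects (named lists as in [synthetic_spec()]; effects referencing
#'   variables dropped by scaling are removed).
#' @param prevalence target expected outcome prevalence (default 358/801).
#' @return a [synthetic_spec()].
#' @export
survey_spec <- function(scale = 1, seed = 1, main_effects = NULL,
                        interaction_effects = NULL,
                        prevalence = 358 / 801) {
  stopifnot(scale > 0, scale <= 1)
  tab <- survey_variable_table()
  keep <- unlist(lapply(split(seq_len(nrow(tab)), tab$group), function(idx)
    idx[seq_len(max(1L, ceiling(length(idx) * scale)))]))
  tab <- tab[sort(keep), , drop = FALSE]
  rownames(tab) <- NULL
  if (is.null(main_effects))
    main_effects <- list(
      region = c(1.3, -1.1, 0.9),       # vs central_chile reference
      income_invested_gt80 = 1.0)
  if (is.null(interaction_effects))
    interaction_effects <- list(
      "region:keep_tradition" = c(1.2, -1.0, 0.8),
      "region:profitable_business" = c(-1.0, 0.9, -0.7))
  main_effects <- main_effects[names(main_effects) %in% tab$variable]
  interaction_effects <- interaction_effects[vapply(
    names(interaction_effects), function(key)
      all(strsplit(key, ":", fixed = TRUE)[[1]] %in% tab$variable), TRUE)]
  intercept <- calibrate_intercept(tab, main_effects, interaction_effects,
                                   prevalence)
  synthetic_spec(round(801 * scale), tab, intercept = intercept,
                 main_effects = main_effects,
                 interaction_effects = interaction_effects, seed = seed)
}
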