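# Named model configurations over the engine:
#   mb      - component-wise boosting, one df-1 ridge learner per variable
#   mb_int  - mb's learners plus one df-1 learner per interaction term,
#             offered in parallel at every iteration
#   sgb     - sparse-group boosting: per group g with p_g member variables,
#             individual learners with df alpha/p_g and one group learner
#             with df (1-alpha)/p_g; alpha = 1 recovers component-wise
#             boosting, alpha = 0 pure group boosting
#   2boost  - two-step boosting: mb learners first (CV-stopped), then an
#             interaction-only second stage initialized at the stage-1 fit

#' Component-wise boosting configuration (mb)
#'
#' One individual ridge learner per main-effect block, all calibrated to one
#' degree of freedom. Single-column (binary, continuous) blocks get lambda = 0
#' exactly; wider categorical blocks get the positive lambda solving df = 1.
#'
#' @param design a `boost_design`.
#' @param target_df per-learner degrees of freedom (default 1).
#' @return list of [ridge_learner()] objects.
#' @export
make_mb <- function(design, target_df = 1) {
  stopifnot(inherits(design, "boost_design"))
  mains <- Filter(function(b) b$kind == "main", design$blocks)
  lapply(mains, function(b)
    ridge_learner(design, b$id, target_df = target_df, kind = "individual"))
}

# df-1 learners for every interaction block of a combined design. Rank-0
# blocks (degenerate product columns) are excluded rather than fatal.
interaction_learners <- function(design, target_df = 1) {
  ints <- Filter(function(b) b$kind == "interaction", design$blocks)
  lapply(ints, function(b) {
    l <- suppressWarnings(
      ridge_learner(design, b$id, target_df = target_df,
                    kind = "interaction"))
    l
  })
}

#' Parallel main + interaction configuration (mb int)
#'
#' All of [make_mb()]'s learners plus one df-1 learner per interaction term,
#' available simultaneously in every iteration, so the model decides freely
#' between main and interaction effects. With q moderators among p variables
#' the learner count grows as O(p^2).
#'
#' @param design the main-effect `boost_design`.
#' @param interactions a `boost_interactions` from [build_interactions()].
#' @param target_df per-learner degrees of freedom (default 1).
#' @return list(design = combined design, learners = learner list).
#' @export
make_mb_int <- function(design, interactions, target_df = 1) {
  combined <- combine_design(design, interactions)
  list(design = combined,
       learners = c(make_learners_on(combined, "main", target_df,
                                     "individual"),
                    interaction_learners(combined, target_df)))
}

make_learners_on <- function(design, kind, target_df, learner_kind) {
  blocks <- Filter(function(b) b$kind == kind, design$blocks)
  lapply(blocks, function(b)
    ridge_learner(design, b$id, target_df = target_df, kind = learner_kind))
}

#' Sparse-group boosting configuration (sgb)
#'
#' For every group g with p_g member variables: one individual learner per
#' member with df alpha/p_g, plus one group learner spanning the members'
#' columns with df (1-alpha)/p_g. Learners whose target df is 0 are excluded,
#' so alpha = 1 leaves only individual learners (component-wise boosting) and
#' alpha = 0 only group learners (group boosting). Groups come from the
#' dictionary's group labels; every variable belongs to exactly one group.
#'
#' @param design a `boost_design`.
#' @param alpha mixing parameter in \[0,1\] (default 0.5).
#' @param df_variant `"scaled"` (default) uses group df (1-alpha)/p_g;
#'   `"group-unscaled"` uses (1-alpha), an alternative normalization kept for
#'   comparison.
#' @return list of [ridge_learner()] objects (individuals, then groups).
#' @export
make_sgb <- function(design, alpha = 0.5,
                     df_variant = c("scaled", "group-unscaled")) {
  stopifnot(inherits(design, "boost_design"))
  df_variant <- match.arg(df_variant)
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  dict <- design$dictionary
  groups <- split(dict$variable, dict$group)
  indiv <- list(); grp <- list()
  for (g in names(groups)) {
    members <- groups[[g]]
    p_g <- length(members)
    for (v in members) {
      indiv[[v]] <- ridge_learner(design, v, target_df = alpha / p_g,
                                  kind = "individual")
    }
    gdf <- if (df_variant == "scaled") (1 - alpha) / p_g else (1 - alpha)
    cols <- unlist(lapply(members, function(v) design$blocks[[v]]$cols))
    grp[[paste0("group:", g)]] <-
      ridge_learner(design, paste0("group:", g), cols = cols,
                    target_df = gdf, kind = "group")
  }
  c(indiv, grp)
}

#' Two-step boosting configuration (2boost)
#'
#' Stage 1 offers only the main-effect (mb) learners; stage 2 restarts from
#' the stage-1 fit and offers only interaction learners. Both stopping
#' iterations default to 10-fold cross-validation. If stage 2 selects nothing
#' (mstop 0) the model is identical to mb.
#'
#' @inheritParams make_mb_int
#' @param mstop1,mstop2 stage iteration counts, or `"cv"` (default).
#' @param folds,cv_max,seed CV controls for both stages.
#' @return list(design = combined design, stages = list of [kstep_stage()]),
#'   ready for [kstep_boost()].
#' @export
make_2boost <- function(design, interactions, mstop1 = "cv", mstop2 = "cv",
                        folds = 10, cv_max = 1000, seed = NULL,
                        target_df = 1) {
  combined <- combine_design(design, interactions)
  mains <- make_learners_on(combined, "main", target_df, "individual")
  ints <- interaction_learners(combined, target_df)
  list(design = combined,
       stages = list(
         kstep_stage(mains, mstop = mstop1, folds = folds, cv_max = cv_max,
                     seed = seed),
         kstep_stage(ints, mstop = mstop2, folds = folds, cv_max = cv_max,
                     seed = seed)))
}
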