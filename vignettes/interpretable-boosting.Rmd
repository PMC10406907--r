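---
title: "Interpretable boosting with df-calibrated ridge base-learners"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpretable boosting with df-calibrated ridge base-learners}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ridgeboost)
```

## The model

ridgeboost fits binary outcomes by component-wise functional gradient
descent on the binomial negative log-likelihood under the logit link,

$$
P(y_i = 1) = \frac{1}{1+\exp(-f_i)}, \qquad
\ell(y, f) = -\sum_i \bigl[y_i \log p_i + (1-y_i)\log(1-p_i)\bigr].
$$

The fit $f$ is built additively. It starts at the constant that minimizes
the loss — the log-odds of the training prevalence (a `zero` option
exists) — and at every iteration

1. evaluates the negative gradient of the loss at the current fit, which for
   this loss is the vector of pseudo-residuals $u_i = y_i - p_i$;
2. fits every *base-learner* to $u$ by ridge-penalized least squares;
3. selects the learner whose fit has the smallest sum of squared errors to
   $u$, and moves the fit by a step of length $\eta$ (default 0.1) along
   that learner's fitted values.

A base-learner is a block of design-matrix columns: one block per variable
(reference-coded, $c-1$ dummy columns for $c$ categories, all columns
centered on the training rows), optionally one block per group of
variables, and one block per moderator-by-variable interaction term (the
elementwise products of the parents' uncentered columns, centered
afterwards). Because only one learner moves per iteration, early stopping
yields variable selection; the selection path, not a penalty on
coefficients, is what enforces sparsity.

### Degrees-of-freedom calibration

Blocks of different widths would compete unfairly: a wider block fits any
response better. The package therefore calibrates each learner's ridge
penalty so that its effective degrees of freedom,

$$
\mathrm{df}(\lambda) = \mathrm{tr}\,(2S - S^{\top}S), \qquad
S = X(X^{\top}X + \lambda I)^{-1}X^{\top},
$$

equals a common target (1 by default). Computationally df is evaluated
through the eigenvalues $d_j$ of $X^\top X$ as
$\sum_j [2 d_j/(d_j+\lambda) - (d_j/(d_j+\lambda))^2]$, and the penalty
solving $\mathrm{df}(\lambda) = \text{target}$ is found by bracketed
bisection on $\log\lambda$ (df is strictly decreasing in $\lambda$),
converged to $10^{-10}$ in df. A single centered column at target df 1 gets
$\lambda = 0$ exactly; for a single column the closed form
$s = 1-\sqrt{1-\mathrm{df}}$, $\lambda = x^\top x\,(1-s)/s$ serves as an
independent check in the tests. A target of 0 marks a learner *excluded*
($\lambda = \infty$, never selectable). When a block is rank-deficient and
its target equals its rank, the penalized solve falls back to the
Moore–Penrose pseudoinverse, i.e. the minimum-norm projection onto the
block's column space.

### The selection rule

The generic algorithm selects the learner minimizing the loss of its fit to
the pseudo-residuals. Applying a binomial likelihood to the continuous
vector $u$ is not well defined, so — following the established model-based
boosting convention — selection minimizes the L2 distance (SSE) between $u$
and the learner's ridge fit. Ties, which can only arise from exactly
duplicated blocks, break toward the lower learner index, which keeps the
path deterministic.

## The four configurations

* **mb** — one individual learner per variable, each at df 1.
* **mb-int** — the mb learners plus one df-1 learner per interaction term,
  all offered in parallel; the model decides freely between main and
  interaction effects. With $q$ moderators among $p$ variables there are
  $q(p-q) + \binom{q}{2}$ interaction terms, $O(p^2)$ learners.
* **sgb** (sparse-group) — per group $g$ with $p_g$ member variables, an
  individual learner per member at df $\alpha/p_g$ and one group learner
  over the members' columns at df $(1-\alpha)/p_g$. The mixing parameter
  $\alpha \in [0,1]$ trades individual against group selection:
  $\alpha = 1$ excludes every group learner (component-wise boosting),
  $\alpha = 0$ every individual learner (group boosting). $p_g$ counts
  member variables, not expanded columns; a variant scaling the group df as
  $1-\alpha$ instead is available as `df_variant = "group-unscaled"`.
* **2boost** — two-step boosting: stage 1 offers only the main-effect
  learners; stage 2 restarts from the stage-1 fit (equivalently, from its
  final pseudo-residual state) and offers only interaction learners. The
  ordering encodes the hierarchy "simple explanations first" and removes
  the selection bias toward the $O(p^2)$ interaction learners that the
  parallel configuration suffers when the expanded interaction design is
  wider than $n$. The engine supports any number of stages with arbitrary
  learner sets (`kstep_boost()`); the 2boost preset is the two-stage case.

## Early stopping

The stopping iteration is chosen by 10-fold cross-validation, stratified by
the outcome, evaluating the out-of-fold mean negative log-likelihood after
every iteration up to a ceiling (`cv_max`, default 1000) and taking the
argmin; exact ties break toward the smaller iteration count, favouring
sparsity. The fitting loss, not AUC, is used as the fold risk. Base-learner
penalties are calibrated once on the full training design and held fixed
across folds; only the blocks' cross products are recomputed per fold.

For multi-stage fits the CV is *fold-honest*: when stage $k$'s stopping
iteration is selected, the earlier stages are refit inside every training
partition (at their already-chosen iteration counts) before the stage-$k$
out-of-fold curve is computed. Conditioning instead on the full-training
earlier-stage fit would leak the held-out rows into the fold initialization
and systematically overstate the useful length of later stages. The final
model still builds on the full-training stage-1 fit, fitted once and
reused.

## Interpretation tools

**Variable importance.** Each iteration's drop in in-sample negative
log-likelihood is credited to the learner selected there and aggregated per
term; the reported percentages are shares of the total reduction. The
absolute reductions reconcile exactly (to $10^{-9}$) with the ends of the
risk path, for all presets including concatenated multi-stage fits, where
percentages are taken relative to the combined reduction with a per-stage
label. Importance uses the unpenalized likelihood the engine tracks, not
the ridge objective.

**Aggregated effects.** Per term and column, the learning-rate-scaled
coefficient increments are summed over the path; exponentiation gives odds
ratios against the reference category. Never-selected terms have odds ratio
exactly 1.

**Partial effects.** Predicted probabilities as one term's category varies
with every other term fixed at its average training contribution. Averages
are taken on the link scale per term (not over raw covariates): because all
design columns are centered, each term's mean training contribution is
zero, so the baseline is the model offset and the offset-only model yields
a flat profile at the training prevalence. This definition is well defined
for categorical blocks, which a raw-covariate average is not.

**Interaction profiles.** A descriptive companion to the boosted screen:
for one moderator–partner pair at a time, a classical logistic regression
with both mains and their interaction is fit (saturated for binary-by-
binary, where fitted cell probabilities equal observed cell proportions)
and fitted probabilities are reported per joint category, optionally per
stratum. Empty joint cells are flagged and their probability omitted rather
than extrapolated.

## Evaluation

Data are split 70/30 into training and test parts before any fitting,
stratified by outcome, with the training count per stratum rounded half-up
(801 observations give 561/240). AUC is computed rank-based
(Mann–Whitney), ties counted one half — the convention under which a
constant predictor scores exactly 0.5 — and equals the trapezoidal area
under the stored empirical ROC curve to machine precision.

## The synthetic survey generator

Because the motivating farm-household survey is not publicly deposited, the
package ships a generator emulating its statistical shape: at `scale = 1`,
801 observations and 75 mostly binary variables in 10 named asset groups
(climate experience, natural, social, human, biophysical, economic, goals,
harm, spatial, norms), one 4-category geography variable, one 3-category
norms item, and 22 flagged moderators — 1397 variable-level interaction
terms, whose expanded columns exceed $n$. Category probabilities loosely
mimic realistic farm-survey marginals. The outcome is drawn from a logistic
model with planted effects; the defaults are region main effects
$(1.3, -1.1, 0.9)$ against the first region, one economic main effect
$(1.0)$, and two region-by-goal interactions
$(1.2, -1.0, 0.8)$ / $(-1.0, 0.9, -0.7)$. The main-effect magnitudes were
calibrated once so that component-wise boosting reaches a held-out AUC in
the 0.7–0.85 range typical of such surveys; the intercept is calibrated
deterministically (fixed-seed Monte Carlo plus root-finding) so the
expected prevalence is 358/801. The truth record keeps each row's exact
linear predictor, so estimators can be validated against the generating
model.

What the generator does *not* emulate: covariates are drawn independently
by default (real survey items are correlated within and across groups),
there is no missingness, no survey weighting, and marginals are matched
only loosely. Passing recovery tests on these data therefore demonstrates
correctness of the machinery under clean conditions, not performance on
real survey data; correlated covariates generally make selection harder.

## Reference problem sizes in the shipped checks

The test suite exercises the engine against independent oracles at small
sizes (selection paths against a brute-force per-step refit on 100 random
fixtures with $n \le 80$, $p \le 12$; AUC against $O(n^2)$ pair counting;
df against a dense hat matrix) and the full pipeline at the reference
scale: planted-effect recovery uses 20 generator seeds at $n = 801$ with
fixed stopping (150 main-stage, 50 interaction-stage iterations), and the
parallel-versus-two-step comparison uses 20 replicates at scale 1 with
10-fold CV capped at 600 iterations per stage — the ceiling we use for
full-scale comparisons throughout, chosen as a practical search range for
this problem size.

## Numerical and design choices

* Reference coding with the first listed category as reference keeps
  binary blocks one column wide, so the dominant binary variables carry
  df 1 without shrinkage.
* Centering is part of design construction; test rows are mapped with the
  training means, never re-centered.
* Moderator–moderator pairs are included once (unordered); a switch removes
  them. Missing values are rejected, not imputed. Constant columns are
  rejected because df calibration is undefined for them.
* Interaction blocks are pure products of the parents' columns. An
  alternative (not implemented) is to span the parents' joint factor space,
  which gives interaction learners strictly more capacity than either
  parent; under product coding the parallel model retains main effects
  noticeably longer than joint-space coding would.
* The intercept is never selectable; it lives in the offset.
* A Gaussian-loss mode exists as a test hook so one-step fits can be
  compared to closed-form least squares; it is not part of the modelling
  surface.
* Importance display filters (at least 1% contribution, at most 15 terms)
  are plotting options, not properties of the table.

## Limitations

Boosted coefficient paths do not come with p-values or standard errors;
importance is a descriptive decomposition of the achieved likelihood
reduction, not a significance statement. AUC does not assess calibration.
Only binomial (and the Gaussian test hook) losses are implemented; no
spline or other nonlinear base-learners are provided.
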