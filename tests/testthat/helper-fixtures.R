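# Fixtures and independent oracles used across the suite.

# A small dictionary: one binary, one 3-category, one 4-category (moderator),
# one continuous variable, in two groups.
tiny_dictionary <- function() {
  as_dictionary(data.frame(
    variable = c("irrigated", "soil", "region", "rainfall"),
    type = c("binary", "categorical", "categorical", "continuous"),
    categories = I(list(c("no", "yes"), c("clay", "loam", "sand"),
                        c("r1", "r2", "r3", "r4"), character(0))),
    group = c("farm", "farm", "geo", "geo"),
    is_moderator = c(FALSE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE))
}

tiny_data <- function(n = 40, seed = 7) {
  d <- tiny_dictionary()
  out <- with_seed_local(seed, data.frame(
    irrigated = sample(c("no", "yes"), n, TRUE),
    soil = sample(c("clay", "loam", "sand"), n, TRUE),
    region = sample(c("r1", "r2", "r3", "r4"), n, TRUE),
    rainfall = rnorm(n),
    stringsAsFactors = FALSE))
  out
}

# local seeded evaluation that restores the RNG state afterwards
with_seed_local <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Random all-binary dictionary with q moderators among p variables.
random_binary_dictionary <- function(p, q = 0, groups = 2) {
  as_dictionary(data.frame(
    variable = paste0("v", seq_len(p)),
    type = "binary",
    categories = I(replicate(p, c("no", "yes"), simplify = FALSE)),
    group = paste0("g", rep_len(seq_len(groups), p)),
    is_moderator = seq_len(p) <= q,
    stringsAsFactors = FALSE))
}

random_binary_data <- function(n, p, seed, signal = NULL) {
  with_seed_local(seed, {
    dat <- as.data.frame(replicate(p, sample(c("no", "yes"), n, TRUE),
                                   simplify = FALSE),
                         stringsAsFactors = FALSE)
    names(dat) <- paste0("v", seq_len(p))
    lp <- rep(0, n)
    if (!is.null(signal))
      for (v in names(signal)) lp <- lp + signal[[v]] * (dat[[v]] == "yes")
    dat$outcome <- rbinom(n, 1, plogis(lp))
    dat
  })
}

# Independent re-implementation of one boosting run: refits every learner at
# every step with an explicit penalized least-squares solve, selects by
# minimum SSE (ties toward the lowest learner index), updates f by eta times
# the winner's fitted values. Used as the selection-path oracle.
brute_force_boost <- function(X, y, learners, eta, mstop, f0,
                              family = "binomial") {
  n <- nrow(X)
  f <- rep(f0, n)
  path <- integer(mstop)
  risk <- function(f) {
    if (family == "binomial") sum(pmax(f, 0) + log1p(exp(-abs(f))) - y * f)
    else 0.5 * sum((y - f)^2)
  }
  risk_path <- numeric(mstop + 1)
  risk_path[1] <- risk(f)
  for (m in seq_len(mstop)) {
    u <- if (family == "binomial") y - plogis(f) else y - f
    sse <- rep(Inf, length(learners))
    fits <- vector("list", length(learners))
    for (r in seq_along(learners)) {
      l <- learners[[r]]
      if (l$excluded) next
      B <- X[, l$cols, drop = FALSE]
      beta <- solve(crossprod(B) + diag(l$lambda, ncol(B)), crossprod(B, u))
      fits[[r]] <- drop(B %*% beta)
      sse[r] <- sum((u - fits[[r]])^2)
    }
    r_star <- which.min(sse)
    path[m] <- r_star
    f <- f + eta * fits[[r_star]]
    risk_path[m + 1] <- risk(f)
  }
  list(path = path, f = f, risk_path = risk_path)
}

# O(n^2) pairwise AUC oracle with half-credit for ties.
pairwise_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (s in pos) total <- total + sum(s > neg) + 0.5 * sum(s == neg)
  total / (length(pos) * length(neg))
}

# Explicit dense ridge hat matrix degrees of freedom: tr(2S - S'S).
hat_matrix_df <- function(X, lambda) {
  S <- X %*% solve(crossprod(X) + diag(lambda, ncol(X)), t(X))
  sum(diag(2 * S - crossprod(S)))
}
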