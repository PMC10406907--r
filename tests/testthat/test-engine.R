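test_that("negative gradient equals observed minus predicted probability", {
  expect_equal(negative_gradient(1, 0), 0.5)
  expect_equal(negative_gradient(0, 40), -1, tolerance = 1e-12)
  # numeric differentiation oracle on random inputs
  with_seed_local(10, {
    y <- rbinom(50, 1, 0.5)
    f <- rnorm(50)
  })
  nll <- function(f) sum(pmax(f, 0) + log1p(exp(-abs(f))) - y * f)
  h <- 1e-6
  numgrad <- vapply(seq_along(f), function(i) {
    fp <- f; fm <- f
    fp[i] <- f[i] + h; fm[i] <- f[i] - h
    -(nll(fp) - nll(fm)) / (2 * h)
  }, 0)
  expect_equal(negative_gradient(y, f), numgrad, tolerance = 1e-6)
})

test_that("the offset is the loss-minimizing constant", {
  expect_equal(init_offset(rep(c(0, 1), 10)), 0)
  y_prev <- c(rep(1, 358), rep(0, 801 - 358))
  expect_equal(init_offset(y_prev), log(358 / 443))
  expect_error(init_offset(rep(1, 20)), "single class")
  # beats every constant on a fine grid
  with_seed_local(11, y <- rbinom(200, 1, 0.3))
  off <- init_offset(y)
  grid <- seq(-4, 4, length.out = 1000)
  nll <- function(f) sum(pmax(f, 0) + log1p(exp(-abs(f))) - y * f)
  expect_true(all(nll(off) <= vapply(grid, nll, 0) + 1e-12))
})

test_that("mstop 0 or all-excluded learners give the offset-only model", {
  dict <- random_binary_dictionary(4)
  dat <- random_binary_data(60, 4, seed = 12)
  des <- build_design(dat, dict)
  y <- dat$outcome
  fit0 <- boost(des, y, make_mb(des), mstop = 0)
  expect_length(fit0$selection_path, 0)
  expect_equal(unique(predict(fit0, type = "response")), mean(y))
  excluded <- lapply(paste0("v", 1:4), function(v)
    ridge_learner(des, v, target_df = 0))
  expect_warning(fit_e <- boost(des, y, excluded, mstop = 10),
                 "excluded")
  expect_length(fit_e$selection_path, 0)
})

test_that("Gaussian mode with one learner, lambda 0, eta 1 is exactly OLS", {
  des <- build_design(tiny_data(40, seed = 13), tiny_dictionary())
  y <- with_seed_local(14, rnorm(40, des$values[, "rainfall"]))
  l <- list(ridge_learner(des, "rainfall", target_df = 1))
  fit <- boost(des, y, l, eta = 1, mstop = 1, family = "gaussian")
  ols <- lm(y ~ des$values[, "rainfall"])
  expect_equal(fit$offset + des$values[, "rainfall"] *
                 unname(coef(fit)["rainfall"]),
               unname(fitted(ols)), tolerance = 1e-10)
})

test_that("selection path matches the brute-force per-step refit oracle", {
  for (seed in 1:10) {
    p <- 4 + seed %% 5
    dict <- random_binary_dictionary(p, q = min(2, p - 1))
    dat <- random_binary_data(60, p, seed = 100 + seed,
                              signal = list(v1 = 1.2))
    des <- build_design(dat, dict)
    cfg <- make_mb_int(des, build_interactions(des))
    y <- dat$outcome
    fit <- boost(cfg$design, y, cfg$learners, eta = 0.1, mstop = 25)
    oracle <- brute_force_boost(cfg$design$values, y, cfg$learners,
                                eta = 0.1, mstop = 25,
                                f0 = init_offset(y))
    ids <- vapply(cfg$learners, `[[`, "", "id")
    expect_identical(fit$selection_path, ids[oracle$path])
    expect_equal(fit$risk_path, oracle$risk_path, tolerance = 1e-10)
  }
})

test_that("in-sample risk is non-increasing and the fit reconstructs", {
  for (seed in 1:5) {
    dict <- random_binary_dictionary(6, q = 2)
    dat <- random_binary_data(80, 6, seed = 200 + seed)
    des <- build_design(dat, dict)
    fit <- boost(des, dat$outcome, make_mb(des), eta = 0.1, mstop = 40)
    expect_true(all(diff(fit$risk_path) <= 1e-10))
    expect_equal(fitted(fit),
                 fit$offset + drop(des$values %*% coef(fit)),
                 tolerance = 1e-10)
  }
})

test_that("predictions respect scale and design compatibility", {
  dict <- random_binary_dictionary(5)
  dat <- random_binary_data(70, 5, seed = 15, signal = list(v2 = 1))
  des <- build_design(dat, dict)
  fit <- boost(des, dat$outcome, make_mb(des), mstop = 30)
  pr <- predict(fit, newdata = dat, type = "response")
  expect_true(all(pr > 0 & pr < 1))
  expect_equal(predict(fit, newdata = dat, type = "link"), fitted(fit),
               tolerance = 1e-12)
  expect_error(predict(fit, newdata = matrix(0, 3, 2)), "design columns")
})

test_that("cross-validated stopping is the argmin of the CV risk curve", {
  dict <- random_binary_dictionary(6)
  dat <- random_binary_data(150, 6, seed = 16, signal = list(v1 = 1.5))
  des <- build_design(dat, dict)
  m <- cv_mstop(des, dat$outcome, make_mb(des), folds = 5, cv_max = 40,
                seed = 1)
  curve <- attr(m, "cv_risk")
  expect_equal(as.integer(m), which.min(curve) - 1L)
  # out-of-fold risk at the chosen mstop is no worse than at m = 0
  expect_lte(curve[as.integer(m) + 1L], curve[1L])
  # deterministic given the seed
  m2 <- cv_mstop(des, dat$outcome, make_mb(des), folds = 5, cv_max = 40,
                 seed = 1)
  expect_identical(as.integer(m), as.integer(m2))
})

test_that("pure-noise outcomes stop early under cross-validation", {
  ms <- vapply(1:8, function(seed) {
    dat <- random_binary_data(200, 6, seed = 300 + seed)
    des <- build_design(dat, random_binary_dictionary(6))
    as.integer(cv_mstop(des, dat$outcome, make_mb(des), folds = 5,
                        cv_max = 60, seed = seed))
  }, 0L)
  expect_lte(median(ms), 3)  # <= 5% of cv_max
})
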