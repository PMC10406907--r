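test_that("df_from_lambda matches closed forms and the dense hat matrix", {
  # lambda = 0 on a full-rank block gives df = number of columns
  X <- with_seed_local(1, matrix(rnorm(60), 20, 3))
  expect_equal(df_from_lambda(X, 0), 3)
  # rank-1 closed form: s = x'x/(x'x + lambda), df = 2s - s^2
  x <- matrix(10, 1, 1)  # x'x = 100
  expect_equal(df_from_lambda(x, 100), 2 * 0.5 - 0.25)
  expect_equal(df_from_lambda(x, 100), hat_matrix_df(x, 100),
               tolerance = 1e-12)
  # spectral formula agrees with the explicit hat matrix on random blocks
  for (seed in 1:5) {
    B <- with_seed_local(seed, matrix(rnorm(40 * 4), 40, 4))
    for (lam in c(0.3, 2, 50))
      expect_equal(df_from_lambda(B, lam), hat_matrix_df(B, lam),
                   tolerance = 1e-8)
  }
  # limits: lambda -> Inf gives 0, and df is strictly decreasing in lambda
  expect_equal(df_from_lambda(X, Inf), 0)
  lams <- c(0, 10^seq(-2, 6, length.out = 30))
  dfs <- vapply(lams, function(l) df_from_lambda(X, l), 0)
  expect_true(all(diff(dfs) < 0))
})

test_that("lambda_from_df inverts df to high precision", {
  # a single centered column at target df 1 forces lambda = 0
  x <- with_seed_local(2, matrix(scale(rnorm(30), scale = FALSE), ncol = 1))
  expect_equal(lambda_from_df(x, 1), 0)
  # rank-1 closed form: target 0.5 -> s = 1 - sqrt(0.5),
  # lambda = x'x (1 - s)/s ~ 241.42 for x'x = 100
  x100 <- matrix(10, 1, 1)
  s <- 1 - sqrt(0.5)
  lam_closed <- 100 * (1 - s) / s
  expect_equal(lam_closed, 241.4214, tolerance = 1e-4)
  expect_equal(lambda_from_df(x100, 0.5), lam_closed, tolerance = 1e-4)
  expect_equal(df_from_lambda(x100, lambda_from_df(x100, 0.5)), 0.5,
               tolerance = 1e-8)
  # 3-column orthonormal block: equal eigenvalues, closed-form root of
  # 3(2s - s^2) = 1
  Q <- qr.Q(qr(with_seed_local(3, matrix(rnorm(90), 30, 3))))
  lam <- lambda_from_df(Q, 1)
  s_target <- 1 - sqrt(1 - 1 / 3)   # per-eigenvalue shrinkage
  expect_equal(lam, (1 - s_target) / s_target, tolerance = 1e-6)
  expect_equal(df_from_lambda(Q, lam), 1, tolerance = 1e-8)
  # errors
  expect_error(lambda_from_df(Q, 4), "rank")
})

test_that("calibration attains the target df on random blocks", {
  for (seed in 1:10) {
    k <- 1 + seed %% 4
    B <- with_seed_local(seed, matrix(rnorm(50 * k), 50, k))
    target <- runif(1, 0.05, k)
    lam <- lambda_from_df(B, target)
    expect_lt(abs(df_from_lambda(B, lam) - target), 1e-6)
  }
})

test_that("fit_base_learner solves the penalized normal equations", {
  des <- build_design(tiny_data(50, seed = 5), tiny_dictionary())
  # lambda = 0 single column: ordinary least-squares slope
  l1 <- ridge_learner(des, "irrigated", target_df = 1)
  expect_equal(l1$lambda, 0)
  u <- with_seed_local(4, rnorm(50))
  x <- des$values[, l1$cols]
  res <- fit_base_learner(l1, des$values[, l1$cols, drop = FALSE], u)
  expect_equal(res$coef, sum(x * u) / sum(x^2))
  # u orthogonal to the block gives zero coefficients
  u_perp <- u - x * sum(x * u) / sum(x^2)
  res0 <- fit_base_learner(l1, des$values[, l1$cols, drop = FALSE], u_perp)
  expect_equal(res0$coef, 0, tolerance = 1e-12)
  # random 20 x 2 block with lambda = 3 against a brute-force solve
  B <- with_seed_local(6, matrix(rnorm(40), 20, 2))
  u2 <- with_seed_local(7, rnorm(20))
  lrn <- list(lambda = 3, cols = 1:2, excluded = FALSE)
  got <- fit_base_learner(lrn, B, u2)
  expect_equal(got$coef,
               drop(solve(crossprod(B) + 3 * diag(2), crossprod(B, u2))),
               tolerance = 1e-12)
  expect_equal(got$sse, sum((u2 - B %*% got$coef)^2))
  # excluded learner: zero fit, SSE = sum(u^2)
  skip <- list(lambda = Inf, cols = 1:2, excluded = TRUE)
  expect_equal(fit_base_learner(skip, B, u2)$sse, sum(u2^2))
})

test_that("calibrated learners report df consistent with their block", {
  des <- build_design(tiny_data(80, seed = 8), tiny_dictionary())
  for (id in c("soil", "region")) {
    l <- ridge_learner(des, id, target_df = 1)
    expect_gt(l$lambda, 0)  # multi-column block needs shrinkage for df 1
    expect_equal(
      hat_matrix_df(des$values[, l$cols, drop = FALSE], l$lambda), 1,
      tolerance = 1e-6)
  }
  # target df 0 marks the learner excluded with lambda = Inf
  l0 <- ridge_learner(des, "irrigated", target_df = 0)
  expect_true(l0$excluded)
  expect_identical(l0$lambda, Inf)
})
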