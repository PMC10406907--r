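test_that("importance conserves the total risk reduction for all presets", {
  dict <- random_binary_dictionary(6, q = 2)
  dat <- random_binary_data(120, 6, seed = 40, signal = list(v1 = 1))
  des <- build_design(dat, dict)
  ints <- build_interactions(des)
  y <- dat$outcome
  fits <- list(
    mb = boost(des, y, make_mb(des), mstop = 30),
    sgb = boost(des, y, make_sgb(des, 0.5), mstop = 30),
    mb_int = {
      cfg <- make_mb_int(des, ints)
      boost(cfg$design, y, cfg$learners, mstop = 30)
    },
    two = {
      cfg <- make_2boost(des, ints, mstop1 = 20, mstop2 = 10)
      kstep_boost(cfg$design, y, cfg$stages)
    })
  for (fit in fits) {
    imp <- variable_importance(fit)
    total <- fit$risk_path[1] - fit$risk_path[length(fit$risk_path)]
    expect_equal(sum(imp$reduction), total, tolerance = 1e-9)
    expect_equal(sum(imp$percent), 100, tolerance = 1e-9)
    expect_true(all(imp$reduction >= 0))
  }
  # K-step tables carry a stage label per row
  expect_setequal(unique(variable_importance(fits$two)$step), c(1, 2))
})

test_that("importance credits degenerate and single-learner fits correctly", {
  dict <- random_binary_dictionary(3)
  dat <- random_binary_data(60, 3, seed = 41, signal = list(v1 = 2))
  des <- build_design(dat, dict)
  one <- list(ridge_learner(des, "v1", target_df = 1))
  fit <- boost(des, dat$outcome, one, mstop = 15)
  imp <- variable_importance(fit)
  expect_equal(imp$term, "v1")
  expect_equal(imp$percent, 100)
  empty <- variable_importance(boost(des, dat$outcome, one, mstop = 0))
  expect_equal(nrow(empty), 0)
})

test_that("aggregated effects replay the increment ledger", {
  dict <- random_binary_dictionary(5)
  dat <- random_binary_data(90, 5, seed = 42, signal = list(v2 = 1.5))
  des <- build_design(dat, dict)
  fit <- boost(des, dat$outcome, make_mb(des), eta = 0.1, mstop = 25)
  eff <- aggregated_effects(fit)
  # independent replay: sum eta * increment per column over the path
  replay <- numeric(des$p)
  for (m in seq_along(fit$selection_path)) {
    cols <- des$blocks[[fit$selection_path[m]]]$cols
    replay[cols] <- replay[cols] + fit$eta * fit$increments[[m]]
  }
  expect_equal(eff$coefficient[match(colnames(des$values), eff$column)],
               replay, tolerance = 1e-12)
  expect_equal(eff$odds_ratio, exp(eff$coefficient))
  # never-selected terms have odds ratio exactly 1
  unselected <- setdiff(dict$variable, fit$selection_path)
  expect_true(all(eff$odds_ratio[eff$term %in% unselected] == 1))
})

test_that("partial effects are flat for the null model and shift by beta", {
  dict <- random_binary_dictionary(4)
  dat <- random_binary_data(80, 4, seed = 43, signal = list(v1 = 1.5))
  des <- build_design(dat, dict)
  y <- dat$outcome
  null_fit <- boost(des, y, make_mb(des), mstop = 0)
  pe0 <- partial_effect(null_fit, "v1")
  expect_equal(pe0$probability, rep(mean(y), 2))
  fit <- boost(des, y, make_mb(des), mstop = 30)
  pe <- partial_effect(fit, "v1")
  beta <- sum(coef(fit)[des$blocks[["v1"]]$cols])
  # link-scale gap between the two categories equals the total coefficient
  expect_equal(pe$link[pe$v1 == "yes"] - pe$link[pe$v1 == "no"], beta,
               tolerance = 1e-12)
  # monotone in beta: the "yes" probability rises with a positive effect
  expect_gt(pe$probability[pe$v1 == "yes"], pe$probability[pe$v1 == "no"])
  expect_error(partial_effect(fit, "nope"), "not in the fitted design")
})

test_that("binary-by-binary interaction profiles equal cell proportions", {
  dat <- random_binary_data(300, 3, seed = 44,
                            signal = list(v1 = 1, v2 = -0.5))
  prof <- interaction_profile(dat, dat$outcome, "v1", "v2")
  for (i in seq_len(nrow(prof))) {
    keep <- dat$v1 == prof$v1[i] & dat$v2 == prof$v2[i]
    expect_equal(prof$probability[i], mean(dat$outcome[keep]),
                 tolerance = 1e-9)
  }
  expect_true(all(prof$probability > 0 & prof$probability < 1))
})

test_that("interaction profiles stratify and flag empty cells", {
  dict <- tiny_dictionary()
  dat <- tiny_data(200, seed = 45)
  y <- with_seed_local(46, rbinom(200, 1, 0.4))
  prof <- interaction_profile(dat, y, "irrigated", "soil",
                              dictionary = dict, stratify_by = "region")
  expect_setequal(unique(prof$stratum), c("all", "r1", "r2", "r3", "r4"))
  # 2 x 3 grid per stratum
  expect_equal(nrow(prof), 5 * 6)
  # independence: whole-data cells near the marginal prevalence
  whole <- prof[prof$stratum == "all", ]
  expect_true(all(abs(whole$probability - mean(y)) < 0.25))
  # a forced empty cell is flagged with NA probability
  dat2 <- dat; dat2$irrigated[dat2$soil == "sand"] <- "no"
  prof2 <- interaction_profile(dat2, y, "irrigated", "soil",
                               dictionary = dict)
  gap <- prof2$irrigated == "yes" & prof2$soil == "sand"
  expect_true(all(prof2$empty_cell[gap]))
  expect_true(all(is.na(prof2$probability[gap])))
})

test_that("importance ordering is invariant to term relabeling", {
  dict <- random_binary_dictionary(5)
  dat <- random_binary_data(100, 5, seed = 47, signal = list(v3 = 1.2))
  des <- build_design(dat, dict)
  fit <- boost(des, dat$outcome, make_mb(des), mstop = 25)
  imp <- variable_importance(fit)
  # permute variable order in the dictionary; reductions per term unchanged
  perm <- c(4, 2, 5, 1, 3)
  dict2 <- as_dictionary(dict[perm, ])
  des2 <- build_design(dat, dict2)
  fit2 <- boost(des2, dat$outcome, make_mb(des2), mstop = 25)
  imp2 <- variable_importance(fit2)
  m <- match(imp$term, imp2$term)
  expect_false(anyNA(m))
  expect_equal(imp$reduction, imp2$reduction[m], tolerance = 1e-9)
})
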