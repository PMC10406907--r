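test_that("main-effect blocks use reference coding and are centered", {
  d <- as_dictionary(data.frame(
    variable = "irrigated", type = "binary",
    categories = I(list(c("no", "yes"))), group = "farm",
    is_moderator = FALSE))
  dat <- data.frame(irrigated = c("no", "yes", "yes", "no"))
  des <- build_design(dat, d)
  expect_equal(ncol(des$values), 1L)
  expect_equal(unname(des$values[, 1]), c(-.5, .5, .5, -.5))
  expect_equal(unname(des$column_means), 0.5)

  dict <- tiny_dictionary()
  des <- build_design(tiny_data(), dict)
  # widths: binary 1, 3-cat 2, 4-cat 3, continuous 1
  widths <- vapply(des$blocks, function(b) length(b$cols), 0L)
  expect_equal(unname(widths), c(1L, 2L, 3L, 1L))
  expect_equal(ncol(des$values), 7L)
  # block column sets partition the columns
  expect_setequal(unlist(lapply(des$blocks, `[[`, "cols")),
                  seq_len(des$p))
  expect_equal(max(abs(colMeans(des$values))), 0, tolerance = 1e-12)
})

test_that("design construction rejects bad inputs with named errors", {
  dict <- tiny_dictionary()
  dat <- tiny_data()
  bad <- dat; bad$soil[3] <- "volcanic"
  expect_error(build_design(bad, dict), "soil.*volcanic")
  expect_error(build_design(dat[, -1], dict), "irrigated")
  const <- dat; const$irrigated <- "yes"
  expect_error(build_design(const, dict), "constant.*irrigated")
  na <- dat; na$rainfall[5] <- NA
  expect_error(build_design(na, dict), "missing")
})

test_that("interaction enumeration matches brute-force pair counting", {
  # q moderators among p variables: q(p-q) + q(q-1)/2 unordered pairs
  for (case in list(c(p = 5, q = 2), c(p = 3, q = 1), c(p = 12, q = 5))) {
    p <- case["p"]; q <- case["q"]
    dict <- random_binary_dictionary(p, q)
    dat <- random_binary_data(60, p, seed = p + q)
    des <- build_design(dat, dict)
    ints <- build_interactions(des)
    pairs <- combn(paste0("v", seq_len(p)), 2, simplify = FALSE)
    brute <- sum(vapply(pairs, function(pr)
      any(pr %in% paste0("v", seq_len(q))), TRUE))
    expect_equal(nrow(ints$terms), brute)
    expect_equal(brute, unname(q * (p - q) + q * (q - 1) / 2))
  }
  # without moderator-moderator pairs only q(p-q) remain
  dict <- random_binary_dictionary(5, 2)
  des <- build_design(random_binary_data(50, 5, seed = 1), dict)
  expect_equal(nrow(build_interactions(des, moderator_pairs = FALSE)$terms),
               2 * 3)
})

test_that("interaction columns are centered products of raw parent columns", {
  dict <- tiny_dictionary()
  dat <- tiny_data(60, seed = 11)
  des <- build_design(dat, dict)
  ints <- build_interactions(des)
  raw <- sweep(des$values, 2, des$column_means, "+")
  blk <- ints$blocks[["region:soil"]]
  mc <- des$blocks[["region"]]$cols; pc <- des$blocks[["soil"]]$cols
  expected <- raw[, rep(mc, times = length(pc))] *
    raw[, rep(pc, each = length(mc))]
  expected <- sweep(expected, 2, colMeans(expected), "-")
  expect_equal(unname(ints$values[, blk$cols]), unname(expected),
               tolerance = 1e-12)
  # block width = moderator width x partner width
  expect_length(blk$cols, 3 * 2)
})

test_that("zero moderators yield an empty term list with a warning", {
  dict <- random_binary_dictionary(4, q = 0)
  des <- build_design(random_binary_data(40, 4, seed = 2), dict)
  expect_warning(ints <- build_interactions(des), "no moderator")
  expect_equal(nrow(ints$terms), 0L)
})

test_that("apply_design reuses training centering and rejects new categories", {
  dict <- tiny_dictionary()
  dat <- tiny_data(50, seed = 3)
  des <- build_design(dat, dict)
  combined <- combine_design(des, build_interactions(des))
  # idempotence on training rows, including interaction blocks
  expect_equal(apply_design(combined, dat), combined$values,
               tolerance = 1e-12, ignore_attr = TRUE)
  # a reference-category row maps to minus the stored column means
  ref <- data.frame(irrigated = "no", soil = "clay", region = "r1",
                    rainfall = 0, stringsAsFactors = FALSE)
  expect_equal(drop(apply_design(des, ref)), -des$column_means,
               ignore_attr = TRUE)
  bad <- dat[1:3, ]; bad$region[2] <- "r9"
  expect_error(apply_design(des, bad), "region.*r9")
})

test_that("designs round-trip through CSV files bit-for-bit", {
  dict <- random_binary_dictionary(6, q = 2, groups = 3)
  dat <- random_binary_data(30, 6, seed = 9)
  tmp <- tempfile("design-roundtrip-")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  utils::write.csv(dat, file.path(tmp, "d.csv"), row.names = FALSE)
  write_dictionary(dict, file.path(tmp, "dict.csv"))
  dat2 <- utils::read.csv(file.path(tmp, "d.csv"), stringsAsFactors = FALSE)
  dict2 <- read_dictionary(file.path(tmp, "dict.csv"))
  expect_identical(build_design(dat, dict)$values,
                   build_design(dat2, dict2)$values)
})

test_that("dictionary validation enforces the declared invariants", {
  base <- tiny_dictionary()
  dup <- base; dup$variable[2] <- "irrigated"
  expect_error(as_dictionary(dup), "duplicate")
  onecat <- base; onecat$categories[[1]] <- "no"
  expect_error(as_dictionary(onecat), "invalid category")
  nogroup <- base; nogroup$group[1] <- ""
  expect_error(as_dictionary(nogroup), "group")
})
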