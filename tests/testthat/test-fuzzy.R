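test_that("membership prototypes and bounds behave as evaluative expressions", {
  expect_equal(membership("big", 1), 1)
  expect_equal(membership("small", 0), 1)
  expect_equal(membership("small", 1), 0)
  expect_equal(membership("big", 0), 0)
  expect_equal(membership("medium", 0.5), 1)
  expect_equal(membership("any", c(0, 0.37, 1)), rep(1, 3))
  expect_error(membership("small", 1.2), class = "chclevels_validation_error")
  expect_error(membership("smallish", 0.5), class = "chclevels_validation_error")
})

test_that("modifier monotonicity chain holds pointwise for all base terms", {
  v <- seq(0, 1, length.out = 101)
  mods <- c(
    "extremely", "significantly", "very", "", "more-or-less", "roughly",
    "quite-roughly", "very-roughly"
  )
  for (b in c("small", "medium", "big")) {
    labels <- trimws(paste(mods, b))
    degs <- sapply(labels, function(l) membership(l, v))
    # each widening step dominates the previous pointwise
    for (j in 2:length(labels)) {
      expect_true(all(degs[, j] >= degs[, j - 1] - 1e-12),
        label = paste(labels[j], "dominates", labels[j - 1]))
    }
  }
})

test_that("best expression picks prototypes at the bounds and roundtrips", {
  expect_match(best_expression(0), "small")
  expect_match(best_expression(1), "big")
  expect_equal(best_expression(0.5), "extremely medium")
  # roundtrip through defuzzification stays within the expression granularity
  v <- seq(0, 1, length.out = 101)
  dv <- dee_defuzzify(best_expression(v))
  expect_lte(max(abs(dv - v)), 0.15)
})

test_that("defuzzified values sit at kernel edges and grade with the modifier", {
  expect_equal(dee_defuzzify("medium"), 0.5)
  expect_equal(dee_defuzzify("extremely small") +
    dee_defuzzify("extremely big"), 1)
  expect_lt(dee_defuzzify("very small"), dee_defuzzify("small"))
  expect_lt(dee_defuzzify("small"), dee_defuzzify("roughly small"))
  expect_gt(dee_defuzzify("very big"), dee_defuzzify("big"))
  expect_true(all(dee_defuzzify(expression_catalog()$label) >= 0))
  expect_true(all(dee_defuzzify(expression_catalog()$label) <= 1))
})

test_that("rule learning deduplicates and resolves conflicts conservatively", {
  one <- dplyr::bind_cols(profile_tbl(rep(0.2, 5)), tibble::tibble(value = 0.9))
  rb <- learn_rules(one)
  expect_identical(nrow(rb), 1L)
  # duplicate observations collapse to a single rule
  two <- dplyr::bind_rows(one, one)
  expect_identical(nrow(learn_rules(two)), 1L)
  # identical inputs, extreme conflicting outputs: one rule survives
  conflict <- dplyr::bind_rows(
    dplyr::mutate(one, value = 0),
    dplyr::mutate(one, value = 1)
  )
  rbc <- learn_rules(conflict)
  expect_identical(nrow(rbc), 1L)
  # tie broken toward the lower defuzzified output (easier level)
  expect_match(rbc$consequent, "small")
})

test_that("rule filtering is idempotent, majority-based, never grows the base", {
  expect_identical(nrow(filter_rules(tibble::tibble())), 0L)
  one <- dplyr::bind_cols(profile_tbl(rep(0.2, 5)), tibble::tibble(value = 0.9))
  raw <- dplyr::bind_rows(
    one, one, one, # 3 copies -> consequent from 0.9
    dplyr::mutate(one, value = 0.1) # 1 conflicting observation
  )
  rb <- learn_rules(raw)
  expect_identical(nrow(rb), 1L)
  expect_identical(rb$consequent, best_expression(0.9))
  expect_identical(filter_rules(rb), rb)
  big <- learn_rules(dplyr::bind_cols(
    profile_tbl(matrix(runif(50 * 5), 50)), tibble::tibble(value = runif(50))
  ))
  expect_lte(nrow(filter_rules(big)), nrow(big))
})

test_that("perception-based deduction fires the best-matching, most specific rule", {
  obs <- dplyr::bind_cols(profile_tbl(rep(0.15, 5)), tibble::tibble(value = 0.3))
  rb <- learn_rules(obs)
  fired <- pbld_infer(rb, rep(0.15, 5))
  expect_identical(fired$index, 1L)
  expect_gt(fired$degree, 0)
  # dominant degree wins over a weaker rule
  rb2 <- filter_rules(tibble::tibble(
    ao = c("small", "big"), mem = c("small", "big"), flu = c("small", "big"),
    lan = c("small", "big"), vis = c("small", "big"),
    consequent = c("small", "big")
  ))
  win <- pbld_infer(rb2, rep(0.05, 5))
  expect_identical(win$rule$consequent, "small")
  # equal degree 1, differing specificity: the narrower antecedent wins
  rb3 <- filter_rules(tibble::tibble(
    ao = c("roughly small", "very small"), mem = "any", flu = "any",
    lan = "any", vis = "any", consequent = c("medium", "small")
  ))
  tie <- pbld_infer(rb3, c(0.01, 0.5, 0.5, 0.5, 0.5))
  expect_identical(tie$rule$consequent, "small")
  # out-of-experience observation signals "no perception"
  rb4 <- filter_rules(tibble::tibble(
    ao = "big", mem = "big", flu = "big", lan = "big", vis = "big",
    consequent = "big"
  ))
  expect_error(pbld_infer(rb4, rep(0.01, 5)), class = "chclevels_no_perception")
})

test_that("learn-then-infer returns the trained consequent for training points", {
  set.seed(21)
  x <- matrix(runif(40 * 5), 40)
  y <- runif(40)
  obs <- dplyr::bind_cols(profile_tbl(x), tibble::tibble(value = y))
  rb <- learn_rules(obs)
  # keep only observations whose raw rule survived filtering unchanged
  for (i in seq_len(40)) {
    raw_ante <- best_expression(x[i, ])
    match_row <- which(
      rb$ao == raw_ante[1] & rb$mem == raw_ante[2] & rb$flu == raw_ante[3] &
        rb$lan == raw_ante[4] & rb$vis == raw_ante[5]
    )
    if (length(match_row) == 1 &&
        rb$consequent[match_row] == best_expression(y[i]) &&
        rb$n[match_row] == 1) {
      fired <- pbld_infer(rb, x[i, ])
      expect_identical(fired$rule$consequent, best_expression(y[i]))
    }
  }
})

test_that("the fuzzy model reproduces oracle levels on its training grid", {
  v <- seq(0, 1, length.out = 101)
  grid <- diag_profiles(v)
  fes <- fes_learn(grid)
  pred <- predict(fes, grid, type = "level")
  oracle <- recommend_levels(grid)
  agree <- mean(as.matrix(pred[chc_domains()]) ==
    as.matrix(oracle[chc_domains()]))
  expect_gte(agree, 0.85)
  # the all-one profile was in the grid: full saturation, top level everywhere
  top <- predict(fes, diag_profiles(1), type = "level")
  expect_equal(unlist(top[chc_domains()], use.names = FALSE), rep(6L, 9))
  # levels are always valid
  probe <- predict(fes, profile_tbl(matrix(runif(100 * 5), 100)), type = "level")
  lv <- as.matrix(probe[chc_domains()])
  expect_true(all(lv %in% 1:6))
})

test_that("rule bases serialise to text and round-trip predictions exactly", {
  fes <- fes_learn(mlp_training_set(60, seed = 13))
  dir <- withr::local_tempdir()
  write_fes(fes, dir)
  expect_identical(length(list.files(dir, pattern = "^rules_.*\\.txt$")), 9L)
  restored <- read_fes(dir)
  probe <- profile_tbl(matrix(runif(8 * 5), 8))
  expect_equal(predict(restored, probe), predict(fes, probe))
  # the rules themselves survive byte-for-byte
  for (dom in chc_domains()) {
    expect_identical(
      tibble::as_tibble(restored$rulebases[[dom]])[c(
        "ao", "mem", "flu", "lan", "vis", "consequent"
      )],
      tibble::as_tibble(fes$rulebases[[dom]])[c(
        "ao", "mem", "flu", "lan", "vis", "consequent"
      )]
    )
  }
})
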