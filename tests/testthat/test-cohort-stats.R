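test_that("outcome classification uses the inclusive 15-letter rule", {
  expect_identical(classify_outcome(65, 85), "improved")
  expect_identical(classify_outcome(50, 65), "improved")      # exactly 15
  expect_identical(classify_outcome(70, 65), "maintained_worse")
  expect_true(is.na(classify_outcome(NA, 65)))
  expect_error(classify_outcome(-3, 65), "\\[0, 100\\]")
})

test_that("chi-square reproduces printed 2x2 p-values and edge cases", {
  expect_equal(round(chi_square_2x2(two_by_two(10, 7, 4, 13))$p_value, 3),
               0.037)
  expect_equal(round(chi_square_2x2(two_by_two(7, 10, 12, 5))$p_value, 3),
               0.084)
  bal <- chi_square_2x2(two_by_two(5, 5, 5, 5))
  expect_equal(bal$statistic, 0)
  expect_equal(bal$p_value, 1)
  expect_error(chi_square_2x2(two_by_two(0, 0, 3, 4)), "zero margin")
  # agrees with stats::chisq.test without continuity correction
  m <- matrix(c(11, 8, 6, 9), 2, byrow = TRUE)
  ours <- chi_square_2x2(m)
  ref <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-12)
})

test_that("Mann-Whitney: exact enumeration for tiny samples", {
  mw <- mann_whitney(c(1, 2, 3), c(10, 11, 12))
  expect_equal(mw$U, 0)
  expect_equal(mw$p_value, 0.1)          # 2/20 labelings as extreme
  expect_identical(mw$method, "exact")
  expect_equal(mann_whitney(1:10, 1:10)$p_value, 1)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("Mann-Whitney approximation agrees with a permutation oracle", {
  set.seed(31)
  x <- rnorm(17, 0, 1); y <- rnorm(17, 0.6, 1.3)
  mw <- mann_whitney(x, y)
  # permutation oracle: U recomputed under 1e5 random relabelings
  pooled <- c(x, y); n1 <- length(x)
  r <- rank(pooled); mu <- n1 * length(y) / 2
  obs <- abs(sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2 - mu)
  B <- 1e5
  perm <- replicate(B, {
    ix <- sample(length(pooled), n1)
    abs(sum(r[ix]) - n1 * (n1 + 1) / 2 - mu)
  })
  p_perm <- mean(perm >= obs - 1e-12)
  mc_se <- sqrt(p_perm * (1 - p_perm) / B)
  expect_lt(abs(mw$p_value - p_perm), 4 * mc_se + 0.005)
})

test_that("compare_groups picks the right test per variable type", {
  d <- make_cohort(cohort_spec(seed = 5))
  cg <- compare_groups(d)
  expect_s3_class(cg, "comparison_report")
  expect_identical(cg$test[cg$variable == "sfct"], "mann_whitney")
  expect_identical(cg$test[cg$variable == "ez_grade"], "chi_square")
  expect_true(all(cg$p_value > 0 & cg$p_value <= 1, na.rm = TRUE))
  # constant variable flagged, not tested
  d$lacunarity <- 0.4
  cg2 <- compare_groups(d)
  expect_identical(cg2$note[cg2$variable == "lacunarity"],
                   "constant variable")
  expect_error(compare_groups(d[d$group == "improved", ]), "both outcome")
})

test_that("compare_groups reproduces the printed EZ row from its counts", {
  d <- count_cohort(10, 7, 4, 13, "ez_grade", 0L, 1L)
  cg <- compare_groups(d, "ez_grade")
  expect_equal(round(cg$p_value, 3), 0.037)
})

test_that("univariable logistic equals the 2x2 closed form", {
  d <- count_cohort(10, 7, 4, 13, "ez_grade", 0L, 1L)
  r <- univariable_logistic(d, "ez_grade")
  expect_equal(r$odds_ratio, (10 * 13) / (7 * 4), tolerance = 1e-6)
  se <- sqrt(1 / 10 + 1 / 7 + 1 / 4 + 1 / 13)
  expect_equal(r$ci_low, exp(log(r$odds_ratio) - 1.96 * se),
               tolerance = 1e-6)
  expect_equal(r$ci_high, exp(log(r$odds_ratio) + 1.96 * se),
               tolerance = 1e-6)
  # symmetric table
  sym <- count_cohort(5, 5, 5, 5, "dark_halo", 1L, 0L)
  expect_equal(univariable_logistic(sym, "dark_halo")$odds_ratio, 1,
               tolerance = 1e-9)
  # separation flagged, no CI
  sep <- count_cohort(8, 0, 3, 6, "branching", 1L, 0L)
  expect_warning(rs <- univariable_logistic(sep, "branching"),
                 "separation")
  expect_true(rs$separation && is.na(rs$ci_low))
})

test_that("relabeling the outcome groups inverts the OR exactly", {
  d <- make_cohort(cohort_spec(seed = 11))
  r1 <- univariable_logistic(d, "sfct")
  d2 <- d
  d2$group <- ifelse(d$group == "improved", "maintained_worse", "improved")
  r2 <- univariable_logistic(d2, "sfct")
  expect_equal(r1$odds_ratio * r2$odds_ratio, 1, tolerance = 1e-6)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-9)
  # row order invariance
  r3 <- univariable_logistic(d[sample(nrow(d)), ], "sfct")
  expect_equal(r1$odds_ratio, r3$odds_ratio, tolerance = 1e-12)
})

test_that("screening keeps exactly the sub-threshold variables", {
  set.seed(19)
  # one true binary effect among noise predictors
  n <- 120
  x_true <- rbinom(n, 1, 0.5)
  eta <- -0.6 + 1.8 * x_true
  y <- rbinom(n, 1, plogis(eta))
  d <- data.frame(
    group = ifelse(y == 1, "improved", "maintained_worse"),
    ez_grade = ifelse(x_true == 1, 0L, 1L),
    sfct = rnorm(n, 60, 25), cft = rnorm(n, 230, 90),
    lacunarity = runif(n, 0.2, 0.6))
  res <- screen_and_fit_multivariable(d, c("ez_grade", "sfct", "cft",
                                           "lacunarity"))
  expect_true("ez_grade" %in% res$selected)
  uni <- res$univariable
  expect_setequal(res$selected, uni$variable[uni$p_value < 0.1])
  # entry_alpha = 1 admits everything
  all_in <- screen_and_fit_multivariable(d, c("ez_grade", "sfct", "cft",
                                              "lacunarity"),
                                         entry_alpha = 1)
  expect_setequal(all_in$selected, c("ez_grade", "sfct", "cft",
                                     "lacunarity"))
  # threshold monotonicity: raising alpha never drops a variable
  expect_true(all(res$selected %in% all_in$selected))
  # adjusted OR close to univariable when others are pure noise
  adj <- all_in$multivariable
  expect_equal(adj$odds_ratio[adj$variable == "ez_grade"],
               uni$odds_ratio[uni$variable == "ez_grade"],
               tolerance = 0.35)
})

test_that("no variable passing the screen yields an empty selection", {
  set.seed(4)
  d <- data.frame(group = rep(c("improved", "maintained_worse"), each = 40),
                  sfct = rnorm(80, 60, 20))
  # force a null predictor and a tiny alpha
  res <- suppressMessages(
    screen_and_fit_multivariable(d, "sfct", entry_alpha = 1e-6))
  expect_length(res$selected, 0)
  expect_null(res$multivariable)
})

test_that("linear regression of BCVA change recovers a known correlation", {
  # collinear points
  d <- data.frame(bcva_baseline = rep(50, 10), bcva_12m = 50 + 2 * (1:10),
                  sfct = 40 + 3 * (1:10))
  lr <- linear_regression_change(d, "sfct")
  expect_equal(lr$r, 1, tolerance = 1e-9)
  expect_lt(lr$p_value, 1e-9)
  expect_equal(lr$slope, 2 / 3, tolerance = 1e-9)
  # parameter recovery at rho = 0.5, n = 34
  set.seed(8)
  rs <- replicate(40, {
    sfct <- rnorm(34, 65, 30)
    dy <- 0.5 * (sfct - 65) / 30 * 15 + rnorm(34, 0, 15 * sqrt(0.75))
    d <- data.frame(bcva_baseline = rep(50, 34), bcva_12m = 50 + dy,
                    sfct = sfct)
    linear_regression_change(d, "sfct")$r
  })
  expect_equal(mean(rs), 0.5, tolerance = 0.1)
  expect_error(linear_regression_change(
    data.frame(bcva_baseline = 1:5, bcva_12m = 2:6, sfct = rep(7, 5))),
    "constant")
})

test_that("null p-values of the change regression are uniform", {
  set.seed(13)
  ps <- replicate(300, {
    d <- data.frame(bcva_baseline = rep(50, 34),
                    bcva_12m = 50 + rnorm(34, 0, 15),
                    sfct = rnorm(34, 65, 30))
    linear_regression_change(d, "sfct")$p_value
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("EZ subgroup comparison works and has power for a 10-letter shift", {
  d <- make_cohort(cohort_spec(seed = 21))
  res <- ez_subgroup_change(d)
  expect_true(res$p_value > 0 && res$p_value <= 1)
  expect_identical(res$grade0$n + res$grade1$n, 34L)
  # power: +10 letters in grade 0, n = 14 vs 20
  rej <- vapply(1:60, function(s) {
    set.seed(s)
    d <- data.frame(
      bcva_baseline = rep(50, 34),
      bcva_12m = 50 + c(rnorm(14, 10, 12), rnorm(20, 0, 12)),
      ez_grade = c(rep(0L, 14), rep(1L, 20)))
    ez_subgroup_change(d)$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.5)
  expect_error(ez_subgroup_change(
    data.frame(bcva_baseline = 1:4, bcva_12m = 2:5, ez_grade = rep(0L, 4))),
    "both EZ grades")
})
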