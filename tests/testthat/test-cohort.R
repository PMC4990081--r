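test_that("generation is deterministic given config and seed", {
  cfg <- generator_config(n_practices_per_board = c(3, 3, 3),
                          list_size_mean = 120, list_size_sd = 20, seed = 5)
  co1 <- build_cohort(cfg)
  co2 <- build_cohort(cfg)
  expect_identical(co1$patients, co2$patients)
  expect_identical(co1$practices, co2$practices)
  ev1 <- simulate_panel(co1, quarters = -2:0)
  ev2 <- simulate_panel(co2, quarters = -2:0)
  expect_identical(ev1, ev2)
  # per-quarter seeding: a single-quarter call reproduces the same quarter
  ev0 <- simulate_panel(co1, quarters = 0)
  sub <- ev1[ev1$quarter == 0L, ]
  rownames(sub) <- NULL
  expect_identical(ev0, sub)
})

test_that("cohort size matches expectation and degenerate clustering works", {
  cfg <- generator_config(n_practices_per_board = c(14, 13, 13),
                          list_size_mean = 700, list_size_sd = 250, seed = 2)
  co <- build_cohort(cfg)
  expect_equal(nrow(co$practices), 40)
  expect_true(abs(nrow(co$patients) - 40 * 700) < 5 * 250 * sqrt(40))
  expect_true(all(table(co$patients$practice_id) == co$practices$list_size))

  cfg0 <- generator_config(n_practices_per_board = c(2, 2, 2), sigma_u = 0,
                           list_size_mean = 100, list_size_sd = 0, seed = 3)
  co0 <- build_cohort(cfg0)
  expect_true(all(co0$practices$u == 0))
  expect_error(generator_config(n_practices_per_board = c(0, 0, 0)))
})

test_that("sigma_from_icc inverts the observed-scale ICC mapping", {
  expect_equal(sigma_from_icc(0, 0.061), 0)
  s1 <- sigma_from_icc(0.005, 0.061)
  s2 <- sigma_from_icc(0.0126, 0.061)
  s3 <- sigma_from_icc(0.05, 0.061)
  expect_true(s1 < s2 && s2 < s3)
  expect_equal(icc_from_sigma(s2, 0.061), 0.0126, tolerance = 1e-7)

  # simulation round trip: 10000 clusters of 100 at the trial's parameters
  set.seed(41)
  alpha <- solve_intercept(0.061, s2)
  u <- rnorm(10000, 0, s2)
  num <- rbinom(10000, 100, plogis(alpha + u))
  expect_lt(abs(anova_icc(num, rep(100, 10000)) - 0.0126), 0.003)
})

test_that("baseline composite prevalence and indicator rates are calibrated", {
  cfg <- generator_config(n_practices_per_board = c(100, 100, 100),
                          list_size_mean = 700, list_size_sd = 100,
                          seed = 20250923)
  co <- build_cohort(cfg)
  ev <- simulate_panel(co, quarters = 0)
  cnt <- measure_panel(co$patients, ev, quarters = 0)
  agg <- stats::aggregate(cbind(numerator, denominator) ~ indicator, cnt, sum)
  rate <- with(agg, numerator / denominator)
  names(rate) <- agg$indicator
  expect_lt(abs(rate[["composite"]] - 0.061), 0.005)
  pooled <- c(S1 = 0.02045, S2 = 0.07784, S3 = 0.03067, S4 = 0.02663,
              S5 = 0.00840, S6 = 0.04680)
  for (ind in names(pooled))
    expect_lt(abs(rate[[ind]] / pooled[[ind]] - 1), 0.30)
})

test_that("practice-level ICC of the generated composite matches the target", {
  cfg <- generator_config(n_practices_per_board = c(167, 167, 166),
                          list_size_mean = 350, list_size_sd = 50,
                          seed = 77)
  co <- build_cohort(cfg)
  ev <- simulate_panel(co, quarters = 0)
  cnt <- measure_panel(co$patients, ev, quarters = 0)
  comp <- cnt[cnt$indicator == "composite", ]
  expect_lt(abs(anova_icc(comp$numerator, comp$denominator) - 0.0126), 0.004)
})

test_that("injected effects surface at the configured size", {
  # no trend, no clustering, no effects: prevalence equals the configured level
  cfg <- generator_config(n_practices_per_board = c(20, 20, 20),
                          list_size_mean = 400, list_size_sd = 0, sigma_u = 0,
                          pre_trend_or = 1,
                          step_or = c(usual_care = 1, feedback = 1, feedback_bcc = 1),
                          slope_change_or = c(usual_care = 1, feedback = 1,
                                              feedback_bcc = 1),
                          seed = 13)
  co <- build_cohort(cfg)
  alloc <- randomise_practices(
    data.frame(practice_id = co$practices$practice_id,
               board = co$practices$board,
               baseline_rate = runif(nrow(co$practices))),
    seed_group = 1, seed_arm = 2)
  ev <- simulate_panel(co, allocation = alloc)
  cnt <- measure_panel(co$patients, ev)
  comp <- cnt[cnt$indicator == "composite", ]
  rate_q <- tapply(comp$numerator, comp$quarter, sum) /
    tapply(comp$denominator, comp$quarter, sum)
  expect_true(all(abs(rate_q - 0.061) < 0.004))

  # a strong step halves the odds between baseline and the first post quarter
  cfg2 <- generator_config(n_practices_per_board = c(20, 20, 20),
                           list_size_mean = 500, list_size_sd = 0, sigma_u = 0,
                           pre_trend_or = 1,
                           step_or = c(usual_care = 0.5, feedback = 0.5,
                                       feedback_bcc = 0.5),
                           slope_change_or = c(usual_care = 1, feedback = 1,
                                               feedback_bcc = 1),
                           seed = 14)
  co2 <- build_cohort(cfg2)
  alloc2 <- randomise_practices(
    data.frame(practice_id = co2$practices$practice_id,
               board = co2$practices$board,
               baseline_rate = runif(nrow(co2$practices))),
    seed_group = 1, seed_arm = 2)
  ev2 <- simulate_panel(co2, allocation = alloc2)
  cnt2 <- measure_panel(co2$patients, ev2)
  comp2 <- cnt2[cnt2$indicator == "composite", ]
  odds <- function(q) {
    n <- sum(comp2$numerator[comp2$quarter == q])
    d <- sum(comp2$denominator[comp2$quarter == q])
    (n / d) / (1 - n / d)
  }
  expect_lt(abs(odds(1) / odds(0) - 0.5), 0.08)
})

test_that("post-intervention quarters require an allocation", {
  cfg <- generator_config(n_practices_per_board = c(2, 2, 2),
                          list_size_mean = 80, list_size_sd = 0, seed = 6)
  co <- build_cohort(cfg)
  expect_error(simulate_panel(co, quarters = 0:2), "allocation")
  alloc <- randomise_practices(
    data.frame(practice_id = co$practices$practice_id[-1],
               board = co$practices$board[-1],
               baseline_rate = runif(5)),
    seed_group = 1, seed_arm = 2)
  expect_error(simulate_panel(co, allocation = alloc, quarters = 0:2),
               "missing practice")
})
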