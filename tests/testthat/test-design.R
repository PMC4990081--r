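test_that("thirds are near-equal with remainders to the lower thirds", {
  b9 <- data.frame(practice_id = sprintf("p%02d", 1:9),
                   baseline_rate = (1:9) / 100)
  th <- assign_thirds(b9)
  expect_equal(unname(table(th$baseline_third)), rep(3L, 3), ignore_attr = TRUE)
  expect_true(all(th$baseline_third[order(th$baseline_rate)] == rep(1:3, each = 3)))

  b10 <- data.frame(practice_id = sprintf("p%02d", 1:10),
                    baseline_rate = (1:10) / 100)
  expect_equal(as.vector(table(assign_thirds(b10)$baseline_third)), c(4L, 3L, 3L))

  ties <- data.frame(practice_id = sprintf("p%02d", 1:7), baseline_rate = 0.05)
  tt <- table(assign_thirds(ties)$baseline_third)
  expect_lte(diff(range(tt)), 1)
  expect_error(assign_thirds(data.frame(practice_id = character(),
                                        baseline_rate = numeric())), "no practices")
})

test_that("stratified randomisation balances groups and blinds the arm step", {
  set.seed(8)
  b <- data.frame(practice_id = sprintf("P%03d", 1:262),
                  board = sample(c("A", "B", "C"), 262, TRUE,
                                 prob = c(0.23, 0.31, 0.46)),
                  baseline_rate = runif(262, 0.02, 0.10))
  al <- randomise_practices(b, seed_group = 101, seed_arm = 202)
  expect_equal(sort(as.vector(table(al$arm))), c(87L, 87L, 88L))
  strat <- table(al$stratum, al$group)
  expect_true(all(apply(strat, 1, function(x) diff(range(x))) <= 1))
  # determinism
  al2 <- randomise_practices(b, seed_group = 101, seed_arm = 202)
  expect_identical(as.data.frame(al), as.data.frame(al2))
  # arm step is a bijection of the three groups
  expect_setequal(attr(al, "arm_of_group"), trial_arms())

  # nine singleton strata: the remainder-balancing rule forces 3/3/3 arms
  b9 <- data.frame(practice_id = sprintf("q%d", 1:9),
                   board = rep(c("A", "B", "C"), each = 3),
                   baseline_rate = rep(c(0.01, 0.05, 0.09), 3))
  for (s in 1:300) {
    al9 <- randomise_practices(b9, seed_group = s, seed_arm = s + 1)
    expect_equal(as.vector(table(al9$arm)), rep(3L, 3))
  }
})

test_that("design effect and closed-form power reproduce standard results", {
  expect_equal(design_effect(700, 0.0126), 9.8074)
  expect_equal(design_effect(123, 0), 1)
  expect_equal(design_effect(1, 0.3), 1)

  # the trial's design parameters give 93% power
  p <- power_two_proportions_cluster(0.061, relative_reduction = 0.25,
                                     m = 700, icc = 0.0126, k = 85,
                                     alpha = 0.025)
  expect_equal(round(100 * p), 93)

  # null-effect limit of the one-sided-rejection approximation
  p0 <- power_two_proportions_cluster(0.061, p_intervention = 0.061,
                                      m = 700, icc = 0.0126, k = 85,
                                      alpha = 0.025)
  expect_equal(p0, 0.025 / 2, tolerance = 1e-12)

  # icc = 0 reduces to the individually randomised formula
  pr <- power_two_proportions_cluster(0.2, p_intervention = 0.15,
                                      m = 50, icc = 0, k = 20, alpha = 0.05)
  n <- 20 * 50
  byhand <- pnorm(abs(0.05) * sqrt(n / (0.2 * 0.8 + 0.15 * 0.85)) - qnorm(0.975))
  expect_equal(pr, byhand, tolerance = 1e-12)

  # monotonicity: more clusters / bigger effect raise power, icc lowers it
  pw <- function(k, icc, rr) power_two_proportions_cluster(
    0.061, relative_reduction = rr, m = 700, icc = icc, k = k, alpha = 0.025)
  expect_true(all(diff(sapply(c(20, 50, 85, 120), pw, icc = 0.0126, rr = 0.25)) > 0))
  expect_true(all(diff(sapply(c(0, 0.0126, 0.05), function(i) pw(85, i, 0.25))) < 0))
  expect_true(all(diff(sapply(c(0.15, 0.25, 0.35), function(r) pw(85, 0.0126, r))) > 0))
})

test_that("clusters_required is the smallest k reaching the target", {
  k <- clusters_required(0.061, relative_reduction = 0.25, m = 700,
                         icc = 0.0126, alpha = 0.025, target_power = 0.9)
  pw <- function(kk) power_two_proportions_cluster(
    0.061, relative_reduction = 0.25, m = 700, icc = 0.0126, k = kk,
    alpha = 0.025)
  expect_gte(pw(k), 0.9)
  expect_lt(pw(k - 1), 0.9)

  # icc 0, m = 1: agrees with the textbook two-proportion sample size
  k1 <- clusters_required(0.3, p_intervention = 0.2, m = 1, icc = 0,
                          alpha = 0.05, target_power = 0.8)
  n_text <- (qnorm(0.975) + qnorm(0.8))^2 * (0.3 * 0.7 + 0.2 * 0.8) / 0.1^2
  expect_lte(abs(k1 - ceiling(n_text)), 1)

  k_lo <- clusters_required(0.061, relative_reduction = 0.25, m = 700,
                            icc = 0.0126, alpha = 0.025, target_power = 0.9)
  k_hi <- clusters_required(0.061, relative_reduction = 0.25, m = 700,
                            icc = 0.0252, alpha = 0.025, target_power = 0.9)
  expect_gte(k_hi, k_lo)
  expect_error(clusters_required(0.061, relative_reduction = 0.25, m = 700,
                                 icc = 0.0126, target_power = 1), "target_power")
})

test_that("simulated power is calibrated under the null and deterministic", {
  null <- simulate_power(0.061, p_intervention = 0.061, m = 700, icc = 0.0126,
                         k = 85, alpha = 0.05, n_reps = 400, seed = 9)
  expect_gt(null$power, 0.02)
  expect_lt(null$power, 0.09)
  again <- simulate_power(0.061, p_intervention = 0.061, m = 700, icc = 0.0126,
                          k = 85, alpha = 0.05, n_reps = 400, seed = 9)
  expect_identical(null$power, again$power)
  expect_error(simulate_power(0.061, p_intervention = 0.05, m = 700,
                              icc = 0.0126, k = 85, n_reps = 50), "n_reps")
})
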