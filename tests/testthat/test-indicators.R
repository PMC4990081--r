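test_that("single-profile classification matches the indicator definitions", {
  f <- classify_patient_quarter(76, "ORAL_ANTIPSYCHOTIC")
  expect_true(f[["S1_den"]] && f[["S1_num"]])
  expect_true(f[["S3_den"]] && !f[["S3_num"]])
  expect_true(f[["composite_num"]])

  # the "triple whammy": under 75, so no S1/S3
  f <- classify_patient_quarter(70, c("DIURETIC", "ACEI_ARB", "ORAL_NSAID"))
  expect_true(f[["S2_den"]] && f[["S2_num"]])
  expect_false(f[["S1_den"]] || f[["S3_den"]])

  # gastroprotection removes the S3 numerator but not the denominator
  f <- classify_patient_quarter(80, c("ORAL_NSAID", "GASTROPROTECTION"))
  expect_true(f[["S3_den"]])
  expect_false(f[["S3_num"]])
  expect_false(f[["composite_num"]])

  # anticoagulant plus antiplatelet: S6 hit, S5 denominator only
  f <- classify_patient_quarter(60, c("ORAL_ANTICOAGULANT", "ASPIRIN_OR_CLOPIDOGREL"))
  expect_true(f[["S6_den"]] && f[["S6_num"]])
  expect_true(f[["S5_den"]] && !f[["S5_num"]])

  # no risk factors at all
  f <- classify_patient_quarter(50, character())
  expect_false(any(f))

  expect_error(classify_patient_quarter(-1), "age")
  expect_error(classify_patient_quarter(70, "NOT_A_CLASS"), "unknown")
})

test_that("practice-quarter aggregation counts each patient once", {
  prof <- data.frame(age = c(80, 80, 50))
  prof$ORAL_ANTIPSYCHOTIC <- c(TRUE, FALSE, FALSE)
  flags <- classify_profiles(prof)
  counts <- aggregate_practice_quarter(flags, patient_id = c("a", "b", "c"))
  comp <- counts[counts$indicator == "composite", ]
  expect_equal(c(comp$numerator, comp$denominator), c(1, 2))
  s1 <- counts[counts$indicator == "S1", ]
  expect_equal(c(s1$numerator, s1$denominator), c(1, 2))

  # a patient in several numerators contributes once to the composite
  prof2 <- data.frame(age = 80, ORAL_ANTIPSYCHOTIC = TRUE, ORAL_NSAID = TRUE)
  f2 <- classify_profiles(prof2)
  expect_true(f2$S1_num && f2$S3_num)
  c2 <- aggregate_practice_quarter(f2)
  expect_equal(c2$numerator[c2$indicator == "composite"], 1)

  # empty input and duplicate ids
  empty <- aggregate_practice_quarter(classify_profiles(data.frame(age = numeric())))
  expect_true(all(empty$numerator == 0) && all(empty$denominator == 0))
  expect_error(aggregate_practice_quarter(flags, patient_id = c("a", "a", "b")),
               "duplicate")
})

test_that("numerators imply denominators and the composite is a union", {
  prof <- random_profiles(3000, seed = 11)
  flags <- classify_profiles(prof)
  for (ind in indicator_names())
    expect_true(all(flags[[paste0(ind, "_den")]][flags[[paste0(ind, "_num")]]]))
  den_union <- Reduce(`|`, lapply(paste0("S", 1:6, "_den"), function(c) flags[[c]]))
  num_union <- Reduce(`|`, lapply(paste0("S", 1:6, "_num"), function(c) flags[[c]]))
  expect_identical(flags$composite_den, den_union)
  expect_identical(flags$composite_num, num_union)
})

test_that("gastroprotection never increases a numerator; OTHER is inert", {
  prof <- random_profiles(2000, seed = 12)
  base <- classify_profiles(prof)
  protected <- prof
  protected$GASTROPROTECTION <- TRUE
  prot <- classify_profiles(protected)
  for (ind in indicator_names()) {
    col <- paste0(ind, "_num")
    expect_true(all(prot[[col]] <= base[[col]]))
    expect_identical(prot[[paste0(ind, "_den")]], base[[paste0(ind, "_den")]])
  }
  # OTHER-class events change nothing
  withOTHER <- prof
  withOTHER$OTHER <- TRUE
  expect_identical(classify_profiles(withOTHER), base)
})

test_that("panel measurement equals per-patient classification", {
  patients <- data.frame(
    patient_id = c("p1", "p2", "p3", "p4"),
    practice_id = c("A", "A", "A", "B"),
    age_at_q0 = c(80, 70, 50, 66),
    registered = c(TRUE, TRUE, TRUE, FALSE))
  events <- data.frame(
    patient_id = c("p1", "p2", "p2", "p2", "p3", "p4"),
    practice_id = c("A", "A", "A", "A", "A", "B"),
    quarter = 0L,
    drug_class = c("ORAL_ANTIPSYCHOTIC", "DIURETIC", "ACEI_ARB", "ORAL_NSAID",
                   "OTHER", "ORAL_NSAID"))
  counts <- measure_panel(patients, events)
  # p4 is not registered: practice B contributes nothing
  expect_false("B" %in% counts$practice_id[counts$denominator > 0])
  a <- counts[counts$practice_id == "A", ]
  expect_equal(a$numerator[a$indicator == "S1"], 1)   # p1
  expect_equal(a$numerator[a$indicator == "S2"], 1)   # p2 triple whammy
  expect_equal(a$denominator[a$indicator == "composite"], 2)
  expect_equal(a$numerator[a$indicator == "composite"], 2)
  # ages advance one completed year every four quarters
  ev4 <- transform(events, quarter = 4L)
  c4 <- measure_panel(patients, rbind(events, ev4), quarters = 4L)
  expect_equal(c4$denominator[c4$practice_id == "A" & c4$indicator == "S1"], 1)
  expect_error(measure_panel(patients, transform(events, drug_class = "XX")),
               "unknown")
})

test_that("prevalence intervals reproduce a brute-force Wald computation", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(50:5e5, 1)
    k <- rbinom(1, n, runif(1, 0.001, 0.5))
    est <- prevalence_with_ci(k, n)
    p <- k / n
    se <- sqrt(p * (1 - p) / n)
    expect_equal(est$proportion, p, tolerance = 1e-12)
    expect_equal(est$ci_low, max(0, p - qnorm(0.975) * se), tolerance = 1e-12)
    expect_equal(est$ci_high, min(1, p + qnorm(0.975) * se), tolerance = 1e-12)
    expect_true(est$ci_low <= est$proportion && est$proportion <= est$ci_high)
  }
  z <- prevalence_with_ci(0, 100)
  expect_equal(c(z$proportion, z$ci_low), c(0, 0))
  expect_error(prevalence_with_ci(1, 0), "positive")
  expect_error(prevalence_with_ci(5, 4), "numerator")
  # Wilson interval stays inside [0,1] and brackets the estimate
  w <- prevalence_with_ci(1, 10, method = "wilson")
  expect_true(w$ci_low > 0 && w$ci_high < 1)
})
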