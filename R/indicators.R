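#' Drug class codes used by the prescribing-safety indicators
#'
#' Semantic dispensing classes. `OTHER` is carried through input tables but
#' never affects any indicator.
#'
#' @return character vector of the recognised class codes.
#' @export
drug_classes <- function() {
  c("ORAL_ANTIPSYCHOTIC", "ORAL_NSAID", "ASPIRIN_OR_CLOPIDOGREL",
    "ORAL_ANTICOAGULANT", "DIURETIC", "ACEI_ARB", "GASTROPROTECTION", "OTHER")
}

#' Names of the six indicators and the composite
#' @return character vector `c("S1", ..., "S6", "composite")`.
#' @export
indicator_names <- function() c(paste0("S", 1:6), "composite")

# classes that enter indicator logic (OTHER excluded)
active_classes <- function() setdiff(drug_classes(), "OTHER")

#' Classify patient-quarter profiles against the six indicators
#'
#' Applies the indicator definitions to a table of patient-quarter profiles:
#'
#' * S1: aged >= 75 (denominator); oral antipsychotic dispensed (numerator).
#' * S2: aged >= 65 on a diuretic and an ACE inhibitor/ARB (denominator);
#'   oral NSAID dispensed (numerator) -- the "triple whammy". Gastroprotection
#'   does not remove S2 numerators.
#' * S3: aged >= 75 (denominator); oral NSAID without gastroprotection.
#' * S4: aged >= 65 on aspirin/clopidogrel (denominator); oral NSAID without
#'   gastroprotection.
#' * S5: on an oral anticoagulant (denominator); oral NSAID without
#'   gastroprotection.
#' * S6: on an oral anticoagulant (denominator); aspirin/clopidogrel without
#'   gastroprotection.
#'
#' "Currently treated with" and "receives" are both operationalised as at
#' least one dispensed event of the class within the measured quarter. The
#' composite denominator is membership of any indicator denominator; the
#' composite numerator is membership of any indicator numerator.
#'
#' @param profiles data.frame with a numeric `age` column and one logical
#'   column per active drug class (see [drug_classes()]); missing class
#'   columns are treated as all-`FALSE`.
#' @return data.frame of logicals with columns `<ind>_den`, `<ind>_num` for
#'   S1..S6 and `composite`; numerators always imply denominators.
#' @export
classify_profiles <- function(profiles) {
  stopifnot(is.data.frame(profiles), "age" %in% names(profiles))
  age <- profiles$age
  if (anyNA(age) || any(age < 0)) stop("ages must be non-negative and non-missing")
  extra <- setdiff(names(profiles),
                   c("age", "patient_id", "practice_id", "quarter", drug_classes()))
  if (length(extra)) stop("unknown drug class column(s): ",
                          paste(extra, collapse = ", "))
  n <- nrow(profiles)
  has <- function(cls) {
    v <- profiles[[cls]]
    if (is.null(v)) rep(FALSE, n) else as.logical(v)
  }
  antipsych <- has("ORAL_ANTIPSYCHOTIC")
  nsaid     <- has("ORAL_NSAID")
  aplt      <- has("ASPIRIN_OR_CLOPIDOGREL")
  acoag     <- has("ORAL_ANTICOAGULANT")
  diur      <- has("DIURETIC")
  acei      <- has("ACEI_ARB")
  gastro    <- has("GASTROPROTECTION")
  nsaid_unprot <- nsaid & !gastro

  f <- data.frame(
    S1_den = age >= 75,
    S2_den = age >= 65 & diur & acei,
    S3_den = age >= 75,
    S4_den = age >= 65 & aplt,
    S5_den = acoag,
    S6_den = acoag
  )
  f$S1_num <- f$S1_den & antipsych
  f$S2_num <- f$S2_den & nsaid
  f$S3_num <- f$S3_den & nsaid_unprot
  f$S4_num <- f$S4_den & nsaid_unprot
  f$S5_num <- f$S5_den & nsaid_unprot
  f$S6_num <- f$S6_den & aplt & !gastro
  f$composite_den <- f$S1_den | f$S2_den | f$S3_den | f$S4_den | f$S5_den | f$S6_den
  f$composite_num <- f$S1_num | f$S2_num | f$S3_num | f$S4_num | f$S5_num | f$S6_num
  cols <- c(rbind(paste0(indicator_names(), "_den"),
                  paste0(indicator_names(), "_num")))
  f[, cols]
}

#' Classify one patient-quarter
#'
#' Single-profile convenience wrapper around [classify_profiles()].
#'
#' @param age age in completed years at the end of the quarter.
#' @param classes character vector of drug classes dispensed in the quarter.
#' @return named logical vector of denominator/numerator flags.
#' @export
classify_patient_quarter <- function(age, classes = character()) {
  stopifnot(is.numeric(age), length(age) == 1L)
  bad <- setdiff(classes, drug_classes())
  if (length(bad)) stop("unknown drug class(es): ", paste(bad, collapse = ", "))
  prof <- data.frame(age = age)
  for (cls in active_classes()) prof[[cls]] <- cls %in% classes
  unlist(classify_profiles(prof)[1L, ])
}

#' Aggregate patient flags to practice-quarter counts
#'
#' Sums per-patient indicator flags into numerator/denominator counts. Each
#' patient contributes at most once per indicator; the composite counts a
#' patient once however many indicators they trigger.
#'
#' @param flags data.frame as returned by [classify_profiles()].
#' @param patient_id optional vector of patient identifiers (checked for
#'   duplicates); defaults to row order.
#' @return data.frame with columns `indicator`, `numerator`, `denominator`.
#' @export
aggregate_practice_quarter <- function(flags, patient_id = NULL) {
  if (!is.null(patient_id)) {
    stopifnot(length(patient_id) == nrow(flags))
    if (anyDuplicated(patient_id)) stop("duplicate patient ids in one practice-quarter")
  }
  inds <- indicator_names()
  data.frame(
    indicator = inds,
    numerator = vapply(inds, function(i) sum(flags[[paste0(i, "_num")]]), 0),
    denominator = vapply(inds, function(i) sum(flags[[paste0(i, "_den")]]), 0),
    row.names = NULL
  )
}

#' Measure indicator counts over a quarterly event panel
#'
#' Runs the indicator engine over every requested quarter: patients are the
#' measurement base (so 75+ patients enter S1/S3 denominators even with no
#' events that quarter), classes dispensed are taken from the event table, and
#' non-registered patients are excluded before classification. Ages advance by
#' one completed year every four quarters from `age_at_q0`.
#'
#' @param patients data.frame with `patient_id`, `practice_id`, `age_at_q0`
#'   (completed years at the end of quarter 0) and optionally `registered`
#'   (logical, default `TRUE`).
#' @param events data.frame with `patient_id`, `practice_id`, `quarter`,
#'   `drug_class`.
#' @param quarters integer vector of quarters to measure; default all quarters
#'   present in `events`.
#' @return data.frame with one row per practice x quarter x indicator:
#'   `practice_id`, `quarter`, `indicator`, `numerator`, `denominator`.
#' @export
measure_panel <- function(patients, events, quarters = NULL) {
  stopifnot(all(c("patient_id", "practice_id", "age_at_q0") %in% names(patients)),
            all(c("patient_id", "quarter", "drug_class") %in% names(events)))
  bad <- setdiff(unique(events$drug_class), drug_classes())
  if (length(bad)) stop("unknown drug class(es) in events: ",
                        paste(bad, collapse = ", "))
  if (is.null(patients$registered)) patients$registered <- TRUE
  patients <- patients[patients$registered, , drop = FALSE]
  if (anyDuplicated(patients$patient_id)) stop("duplicate patient ids")
  if (is.null(quarters)) quarters <- sort(unique(events$quarter))

  ev <- data.table::as.data.table(events)[
    drug_class != "OTHER" & patient_id %in% patients$patient_id]
  ev <- unique(ev[, list(patient_id, quarter, drug_class)])
  cls <- active_classes()
  np <- nrow(patients)
  prac <- factor(patients$practice_id)

  out <- vector("list", length(quarters))
  for (qi in seq_along(quarters)) {
    q <- quarters[qi]
    sub <- ev[quarter == q]
    has <- matrix(FALSE, np, length(cls), dimnames = list(NULL, cls))
    if (nrow(sub)) {
      ridx <- match(sub$patient_id, patients$patient_id)
      cidx <- match(sub$drug_class, cls)
      has[cbind(ridx, cidx)] <- TRUE
    }
    prof <- data.frame(age = patients$age_at_q0 + floor(q / 4))
    for (k in cls) prof[[k]] <- has[, k]
    flags <- classify_profiles(prof)
    counts <- rowsum(+as.matrix(flags), prac)
    inds <- indicator_names()
    out[[qi]] <- data.frame(
      practice_id = rep(rownames(counts), times = length(inds)),
      quarter = q,
      indicator = rep(inds, each = nrow(counts)),
      numerator = as.vector(counts[, paste0(inds, "_num")]),
      denominator = as.vector(counts[, paste0(inds, "_den")]),
      row.names = NULL
    )
  }
  res <- do.call(rbind, out)
  res <- res[order(res$practice_id, res$quarter, match(res$indicator, indicator_names())), ]
  rownames(res) <- NULL
  res
}

#' Proportion with a binomial confidence interval
#'
#' Point prevalence with a normal-approximation (Wald) interval, clamped to
#' \[0, 1\]; a Wilson score interval is available behind `method`.
#'
#' @param numerator,denominator non-negative counts, `numerator <= denominator`,
#'   `denominator > 0`.
#' @param level confidence level (default 0.95).
#' @param method `"wald"` (default) or `"wilson"`.
#' @return data.frame with `proportion`, `ci_low`, `ci_high`, `n`.
#' @export
prevalence_with_ci <- function(numerator, denominator, level = 0.95,
                               method = c("wald", "wilson")) {
  method <- match.arg(method)
  stopifnot(length(numerator) == length(denominator),
            is.numeric(level), level > 0, level < 1)
  if (any(denominator <= 0)) stop("denominator must be positive")
  if (any(numerator < 0) || any(numerator > denominator))
    stop("need 0 <= numerator <= denominator")
  p <- numerator / denominator
  z <- qnorm(1 - (1 - level) / 2)
  if (method == "wald") {
    se <- sqrt(p * (1 - p) / denominator)
    lo <- p - z * se
    hi <- p + z * se
  } else {
    n <- denominator
    centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    lo <- centre - half
    hi <- centre + half
  }
  data.frame(proportion = p, ci_low = pmax(0, lo), ci_high = pmin(1, hi),
             n = denominator)
}
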