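study_quarters <- function(config) {
  seq.int(-(config$n_quarters_pre - 1L), config$n_quarters_post)
}

# Markov trait panel: chronic classes retained with prob 1 - churn and
# re-acquired at the stationary rate, so marginal prevalences are stable.
# Anticoagulant/antiplatelet exclusivity is preserved by the acquisition rule.
simulate_traits <- function(cohort, quarters) {
  mix <- cohort$config$indicator_mix
  pat <- cohort$patients
  q_min <- min(quarters)
  churn <- mix$churn
  elig65 <- pat$age_at_q0 >= 65  # da/ap carriers are drawn in the 65+ groups

  acq <- function(prev) if (prev >= 1 || churn == 0) 0 else prev * churn / (1 - prev)
  state <- data.frame(da = pat$da, ap = pat$ap, ac = pat$ac)
  prev_da <- mean(state$da[elig65])
  prev_ap <- mean(state$ap[elig65])
  prev_ac <- mean(state$ac)

  out <- vector("list", length(quarters))
  names(out) <- as.character(quarters)
  for (q in quarters) {
    if (q > q_min && churn > 0) {
      set.seed(mix_seed(cohort$config$seed, 5000L + q))
      n <- nrow(state)
      keep <- matrix(runif(3L * n) >= churn, n, 3L)
      gain <- cbind(runif(n) < acq(prev_da), runif(n) < acq(prev_ap),
                    runif(n) < acq(prev_ac))
      da <- ifelse(state$da, keep[, 1L], gain[, 1L]) & elig65
      ap <- ifelse(state$ap, keep[, 2L], gain[, 2L] & !state$ac) & elig65
      ac <- ifelse(state$ac, keep[, 3L], gain[, 3L] & !ap)
      state <- data.frame(da = da, ap = ap, ac = ac)
    }
    out[[as.character(q)]] <- state
  }
  out
}

# per-arm level shift implied by the reported step OR convention
step_delta <- function(step_or, slope_change_or, dt = 0.25) {
  log(step_or) - dt * log(slope_change_or)
}

#' Simulate quarterly prescription events
#'
#' Draws, for every patient-quarter, chronic risk-factor dispensing events and
#' a composite high-risk hazard event with probability
#' \deqn{\mathrm{expit}(\alpha_0 + u_j + \mathrm{off}_i + \gamma t +
#'   \mathbf{1}[t > 0](\delta_{a} + \theta_{a} t))}
#' where \eqn{t} is time in years centred at the baseline quarter,
#' \eqn{u_j} the practice intercept, \eqn{\mathrm{off}_i} the patient's
#' risk-class offset, \eqn{\gamma} the shared pre-intervention trend and
#' \eqn{(\delta_a, \theta_a)} the arm's step and slope change. A fired hazard
#' is realised as one concrete high-risk prescription (unprotected NSAID,
#' antipsychotic for a 75+ patient, gastro-protected NSAID for a triple-whammy
#' patient, or aspirin for an anticoagulated patient) chosen among the
#' patient's eligible channels by the configured action weights, so every
#' composite event is a composite numerator and vice versa. Background
#' gastroprotection, protected NSAIDs and inert `OTHER` events are added where
#' they cannot change any numerator.
#'
#' Per-quarter seeding makes output for a given quarter identical whatever set
#' of quarters is requested, so pre-intervention data do not depend on the
#' allocation.
#'
#' @param cohort a [build_cohort()] result.
#' @param allocation an [randomise_practices()] allocation (required if any
#'   post-intervention quarter is simulated), or `NULL` for no arm effects.
#' @param quarters quarters to simulate; default the full study window.
#' @return data.frame of events: `patient_id`, `practice_id`, `quarter`,
#'   `drug_class`.
#' @export
simulate_panel <- function(cohort, allocation = NULL, quarters = NULL) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  config <- cohort$config
  mix <- config$indicator_mix
  if (is.null(quarters)) quarters <- study_quarters(config)
  quarters <- sort(unique(as.integer(quarters)))
  window <- study_quarters(config)
  if (any(!quarters %in% window)) stop("quarters outside the configured study window")

  pat <- cohort$patients
  n <- nrow(pat)
  u_pat <- cohort$practices$u[match(pat$practice_id, cohort$practices$practice_id)]

  arm_pat <- NULL
  if (any(quarters > 0L)) {
    if (is.null(allocation)) stop("post-intervention quarters need an allocation")
  }
  if (!is.null(allocation)) {
    alloc <- as.data.frame(allocation)
    missing_prac <- setdiff(cohort$practices$practice_id, alloc$practice_id)
    if (length(missing_prac)) stop("allocation missing practice(s): ",
                                   paste(utils::head(missing_prac, 5), collapse = ", "))
    arm_pat <- alloc$arm[match(pat$practice_id, alloc$practice_id)]
  }

  delta <- step_delta(config$step_or, config$slope_change_or)
  theta <- log(config$slope_change_or)
  gamma <- log(config$pre_trend_or)

  traits <- simulate_traits(cohort, seq.int(min(window), max(quarters)))
  out <- vector("list", length(quarters))

  for (qi in seq_along(quarters)) {
    q <- quarters[qi]
    set.seed(mix_seed(config$seed, 100L + q))
    tr <- traits[[as.character(q)]]
    age_q <- pat$age_at_q0 + floor(q / 4)
    e75 <- age_q >= 75
    e65 <- age_q >= 65
    s2den <- e65 & tr$da
    s4den <- e65 & tr$ap
    comp_den <- e75 | s2den | s4den | tr$ac

    t_yr <- q / 4
    eta <- cohort$alpha0 + u_pat + trait_offsets(tr$da, tr$ap, tr$ac, mix) +
      gamma * t_yr
    if (q > 0L && !is.null(arm_pat))
      eta <- eta + delta[arm_pat] + theta[arm_pat] * t_yr
    event <- comp_den & (runif(n) < expit(eta))

    # action choice among eligible hazard channels
    W <- cbind(nsaidu = rep(1, n),
               antipsych = ifelse(e75, mix$w_antipsychotic, 0),
               nsaidp = ifelse(s2den, mix$w_protected_nsaid, 0),
               s6 = ifelse(tr$ac, mix$w_s6, 0))
    cum1 <- W[, 1L]
    cum2 <- cum1 + W[, 2L]
    cum3 <- cum2 + W[, 3L]
    tot <- cum3 + W[, 4L]
    r <- runif(n) * tot
    act_idx <- 1L + (r > cum1) + (r > cum2) + (r > cum3)
    action <- colnames(W)[pmin(act_idx, 4L)]
    action[!event] <- "none"

    unprot <- event & action %in% c("nsaidu", "s6")
    bg_protected <- !event & !s2den & (runif(n) < mix$p_protected_nsaid)
    bg_gastro <- !unprot & !bg_protected & (runif(n) < mix$p_gastro_background)
    other <- runif(n) < mix$p_other

    emit <- function(idx, cls) {
      if (!length(idx)) return(NULL)
      data.table::data.table(patient_id = pat$patient_id[idx],
                             practice_id = pat$practice_id[idx],
                             quarter = q, drug_class = cls)
    }
    pieces <- list(
      emit(which(tr$da), "DIURETIC"),
      emit(which(tr$da), "ACEI_ARB"),
      emit(which(tr$ap), "ASPIRIN_OR_CLOPIDOGREL"),
      emit(which(tr$ac), "ORAL_ANTICOAGULANT"),
      emit(which(event & action == "nsaidu"), "ORAL_NSAID"),
      emit(which(event & action == "antipsych"), "ORAL_ANTIPSYCHOTIC"),
      emit(which(event & action == "nsaidp"), "ORAL_NSAID"),
      emit(which(event & action == "nsaidp"), "GASTROPROTECTION"),
      emit(which(event & action == "s6"), "ASPIRIN_OR_CLOPIDOGREL"),
      emit(which(bg_protected), "ORAL_NSAID"),
      emit(which(bg_protected), "GASTROPROTECTION"),
      emit(which(bg_gastro), "GASTROPROTECTION"),
      emit(which(other), "OTHER")
    )
    out[[qi]] <- data.table::rbindlist(pieces[!vapply(pieces, is.null, TRUE)])
  }
  res <- data.table::rbindlist(out)
  data.table::setkeyv(res, c("practice_id", "patient_id", "quarter", "drug_class"))
  as.data.frame(res)
}

#' Fast practice-level simulation of composite counts
#'
#' Simulates the practice-by-quarter composite numerator/denominator panel
#' directly at cluster level (binomial draws from the same logistic model as
#' [simulate_panel()], without the per-indicator decomposition). Intended for
#' estimator calibration studies where only the composite matters.
#'
#' @param n_practices number of practices.
#' @param patients_per_practice denominator per practice-quarter.
#' @param baseline_p marginal composite prevalence at baseline.
#' @param icc target observed-scale ICC (converted via [sigma_from_icc()]);
#'   ignored when `sigma_u` is given.
#' @param sigma_u optional random-intercept SD on the logit scale.
#' @param pre_trend_or shared secular odds ratio per year.
#' @param step_or,slope_change_or named per-arm odds ratios (reported-step
#'   convention, as in [generator_config()]); names define the arm labels.
#' @param n_quarters_pre,n_quarters_post study window (baseline is the last
#'   pre-intervention quarter).
#' @param seed integer seed.
#' @return data.frame panel: `practice_id`, `quarter`, `t`, `post`, `arm`,
#'   `numerator`, `denominator` (arms dealt round-robin across practices).
#' @export
simulate_counts_panel <- function(n_practices, patients_per_practice,
                                  baseline_p = 0.061, icc = 0.0126,
                                  sigma_u = NULL,
                                  pre_trend_or = 0.92,
                                  step_or = c(usual_care = 1, feedback = 1,
                                              feedback_bcc = 1),
                                  slope_change_or = c(usual_care = 1,
                                                      feedback = 1,
                                                      feedback_bcc = 1),
                                  n_quarters_pre = 6L, n_quarters_post = 5L,
                                  seed = 1L) {
  stopifnot(n_practices >= 2, patients_per_practice >= 1,
            length(step_or) == length(slope_change_or),
            !is.null(names(step_or)))
  set.seed(mix_seed(seed, 17L))
  arms <- names(step_or)
  sigma_u <- sigma_u %||% sigma_from_icc(icc, baseline_p)
  alpha0 <- solve_intercept(baseline_p, sigma_u)
  u <- rnorm(n_practices, 0, sigma_u)
  arm <- rep_len(arms, n_practices)
  delta <- step_delta(step_or, slope_change_or)
  theta <- log(slope_change_or)
  gamma <- log(pre_trend_or)

  quarters <- seq.int(-(n_quarters_pre - 1L), n_quarters_post)
  out <- lapply(quarters, function(q) {
    t_yr <- q / 4
    eta <- alpha0 + u + gamma * t_yr
    if (q > 0L) eta <- eta + delta[arm] + theta[arm] * t_yr
    data.frame(practice_id = sprintf("P%04d", seq_len(n_practices)),
               quarter = q, t = t_yr, post = as.integer(q > 0L), arm = arm,
               numerator = rbinom(n_practices, patients_per_practice, expit(eta)),
               denominator = patients_per_practice)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$practice_id, res$quarter), ]
  rownames(res) <- NULL
  res
}
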