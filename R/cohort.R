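#' Configuration for the synthetic dispensing-data generator
#'
#' Defaults encode the study conditions the generator emulates: 262 practices
#' across three health boards, a mean of 700 at-risk patients per practice, a
#' 6.1% baseline composite prevalence with practice-level intraclass
#' correlation 0.0126 on the observed binary scale, a declining secular trend
#' of OR 0.92 per year, and per-arm step / slope-change effects after the
#' intervention quarter. Eleven quarters are indexed -5..+5 with baseline 0;
#' quarters > 0 are post-intervention and quarter +5 is the 15-month endpoint.
#'
#' `indicator_mix` controls the decomposition of the composite hazard into the
#' six indicators: age-group mix, chronic risk-factor prevalences
#' (diuretic+ACEI/ARB, antiplatelet, anticoagulant; the latter two mutually
#' exclusive), patient-level log-odds offsets by risk class, and the relative
#' weights of the hazard actions realised when a composite event fires
#' (unprotected NSAID, antipsychotic, gastro-protected NSAID, aspirin to an
#' anticoagulated patient). Defaults are calibrated so per-indicator baseline
#' rates sit close to the pooled baseline table of the emulated trial.
#'
#' `step_or` is expressed in the reporting convention of the change-point
#' model: the model-implied odds ratio between the first post-intervention
#' quarter and the last pre-intervention quarter; internally the generator
#' converts to a level shift `delta = log(step_or) - 0.25 * log(slope_change_or)`.
#'
#' @param n_practices_per_board integer vector of length 3.
#' @param list_size_mean,list_size_sd at-risk patients per practice
#'   (truncated normal, minimum 50).
#' @param baseline_p marginal composite prevalence at the baseline quarter.
#' @param target_icc target ANOVA-scale intraclass correlation; used to solve
#'   the random-intercept SD when `sigma_u` is `NULL`.
#' @param sigma_u practice random-intercept SD on the logit scale, or `NULL`.
#' @param pre_trend_or secular odds ratio per year, shared across arms.
#' @param step_or,slope_change_or named per-arm odds ratios
#'   (`usual_care`, `feedback`, `feedback_bcc`).
#' @param n_quarters_pre,n_quarters_post quarters before (including baseline)
#'   and after the change point.
#' @param indicator_mix list; see Details above for fields.
#' @param p_unregistered probability a generated patient is not permanently
#'   registered (excluded from measurement).
#' @param seed integer seed controlling the whole generation.
#' @return object of class `generator_config` (a validated list).
#' @export
generator_config <- function(n_practices_per_board = c(60L, 82L, 120L),
                             list_size_mean = 700,
                             list_size_sd = 250,
                             baseline_p = 0.061,
                             target_icc = 0.0126,
                             sigma_u = NULL,
                             pre_trend_or = 0.92,
                             step_or = c(usual_care = 0.97, feedback = 1.00,
                                         feedback_bcc = 0.96),
                             slope_change_or = c(usual_care = 0.99,
                                                 feedback = 0.87,
                                                 feedback_bcc = 0.88),
                             n_quarters_pre = 6L,
                             n_quarters_post = 5L,
                             indicator_mix = list(),
                             p_unregistered = 0.002,
                             seed = 1L) {
  mix_default <- list(
    f_u65 = 0.08, f_a65 = 0.31,
    q_da = 0.32, q_ap = 0.55, q_ac = 0.035,
    off_da = 0.65, off_ap = -0.65, off_ac = -0.25,
    w_antipsychotic = 0.75, w_protected_nsaid = 1.0, w_s6 = 6.0,
    p_gastro_background = 0.15, p_protected_nsaid = 0.02, p_other = 0.30,
    churn = 0.05
  )
  bad <- setdiff(names(indicator_mix), names(mix_default))
  if (length(bad)) stop("unknown indicator_mix field(s): ", paste(bad, collapse = ", "))
  mix <- utils::modifyList(mix_default, indicator_mix)

  stopifnot(length(n_practices_per_board) == 3L,
            all(n_practices_per_board >= 0),
            sum(n_practices_per_board) >= 1,
            list_size_mean > 0, list_size_sd >= 0,
            baseline_p > 0, baseline_p < 1,
            target_icc >= 0, target_icc < 1,
            is.null(sigma_u) || sigma_u >= 0,
            pre_trend_or > 0,
            length(step_or) == 3L, all(step_or > 0),
            length(slope_change_or) == 3L, all(slope_change_or > 0),
            n_quarters_pre >= 1, n_quarters_post >= 1,
            n_quarters_pre + n_quarters_post >= 2,
            p_unregistered >= 0, p_unregistered < 1)
  probs <- unlist(mix[c("f_u65", "f_a65", "q_da", "q_ap", "q_ac",
                        "p_gastro_background", "p_protected_nsaid", "p_other",
                        "churn")])
  stopifnot(all(probs >= 0), all(probs < 1), mix$f_u65 + mix$f_a65 < 1)
  arms <- c("usual_care", "feedback", "feedback_bcc")
  names(step_or) <- names(step_or) %||% arms
  names(slope_change_or) <- names(slope_change_or) %||% arms
  stopifnot(setequal(names(step_or), arms), setequal(names(slope_change_or), arms))

  structure(list(
    n_practices_per_board = as.integer(n_practices_per_board),
    list_size_mean = list_size_mean, list_size_sd = list_size_sd,
    baseline_p = baseline_p, target_icc = target_icc, sigma_u = sigma_u,
    pre_trend_or = pre_trend_or,
    step_or = step_or[arms], slope_change_or = slope_change_or[arms],
    n_quarters_pre = as.integer(n_quarters_pre),
    n_quarters_post = as.integer(n_quarters_post),
    indicator_mix = mix, p_unregistered = p_unregistered,
    seed = as.integer(seed)
  ), class = "generator_config")
}

#' Trial arm labels
#' @return character vector of the three arm labels, usual care first.
#' @export
trial_arms <- function() c("usual_care", "feedback", "feedback_bcc")

# E[expit(alpha + off + sigma Z)] over Z ~ N(0,1) and a discrete offset
# distribution (values `off`, weights `w` summing to 1)
marginal_p <- function(alpha, sigma, off = 0, w = 1, gh = gauss_hermite(31)) {
  m <- 0
  for (k in seq_along(gh$nodes)) {
    u <- sqrt(2) * sigma * gh$nodes[k]
    m <- m + gh$weights[k] / sqrt(pi) * sum(w * expit(alpha + off + u))
  }
  m
}

#' Solve the conditional intercept for a target marginal prevalence
#'
#' Finds `alpha` such that the population-averaged event probability, with a
#' Normal(0, sigma^2) cluster intercept and an optional discrete distribution
#' of patient-level log-odds offsets, equals `target_p`.
#'
#' @param target_p marginal probability in (0, 1).
#' @param sigma cluster random-intercept SD (logit scale).
#' @param offsets,weights discrete offset distribution (weights sum to 1).
#' @return the intercept `alpha` on the logit scale.
#' @export
solve_intercept <- function(target_p, sigma, offsets = 0, weights = 1) {
  stopifnot(target_p > 0, target_p < 1, sigma >= 0,
            length(offsets) == length(weights), all(weights >= 0))
  weights <- weights / sum(weights)
  gh <- gauss_hermite(31)
  span <- 12 + 8 * sigma + max(abs(offsets))
  uniroot(function(a) marginal_p(a, sigma, offsets, weights, gh) - target_p,
          lower = logit(target_p) - span, upper = logit(target_p) + span,
          tol = 1e-12)$root
}

#' Observed-scale ICC implied by a logit-normal random intercept
#'
#' For a binary outcome with cluster probability
#' \eqn{p(u) = \mathrm{expit}(\alpha + u)}, \eqn{u \sim N(0, \sigma^2)}, the
#' ANOVA (observed binary scale) intraclass correlation is
#' \eqn{\mathrm{Var}_u\,p(u) / (\bar p (1 - \bar p))}. The intercept is
#' re-solved so the marginal mean stays at `baseline_p` for every `sigma`.
#'
#' @param sigma random-intercept SD on the logit scale.
#' @param baseline_p marginal outcome probability.
#' @return the implied observed-scale ICC.
#' @export
icc_from_sigma <- function(sigma, baseline_p) {
  stopifnot(sigma >= 0, baseline_p > 0, baseline_p < 1)
  if (sigma == 0) return(0)
  gh <- gauss_hermite(31)
  alpha <- solve_intercept(baseline_p, sigma)
  m1 <- 0; m2 <- 0
  for (k in seq_along(gh$nodes)) {
    u <- sqrt(2) * sigma * gh$nodes[k]
    pk <- expit(alpha + u)
    wk <- gh$weights[k] / sqrt(pi)
    m1 <- m1 + wk * pk
    m2 <- m2 + wk * pk^2
  }
  (m2 - m1^2) / (m1 * (1 - m1))
}

#' Random-intercept SD achieving a target observed-scale ICC
#'
#' Inverts [icc_from_sigma()] by root finding: returns the logit-scale SD of
#' the practice random intercept under which simulated binary outcomes have
#' the requested ANOVA intraclass correlation at marginal prevalence
#' `baseline_p`.
#'
#' @param target_icc requested ICC in \[0, 1).
#' @param baseline_p marginal outcome probability.
#' @return `sigma_u` on the logit scale.
#' @export
sigma_from_icc <- function(target_icc, baseline_p) {
  stopifnot(target_icc >= 0, target_icc < 1, baseline_p > 0, baseline_p < 1)
  if (target_icc == 0) return(0)
  upper <- 40
  if (icc_from_sigma(upper, baseline_p) < target_icc)
    stop("target ICC unattainable at this prevalence")
  uniroot(function(s) icc_from_sigma(s, baseline_p) - target_icc,
          lower = 1e-8, upper = upper, tol = 1e-10)$root
}

# patient-level log-odds offset from chronic risk classes
trait_offsets <- function(da, ap, ac, mix) {
  mix$off_da * da + mix$off_ap * ap + mix$off_ac * ac
}

#' Generate a synthetic practice/patient cohort
#'
#' Builds the cluster scaffolding every downstream stage consumes: practices
#' with board labels, list sizes and i.i.d. Normal(0, sigma_u^2) random
#' intercepts; and at-risk patients with ages, sex, deprivation fifth,
#' registration flag, and chronic risk-factor classes (diuretic+ACEI/ARB,
#' antiplatelet, anticoagulant) drawn from `indicator_mix`. Patients under 65
#' are anticoagulated (their only route into a denominator); 65-74 year olds
#' are redrawn until they carry at least one risk factor; anticoagulant and
#' chronic antiplatelet are mutually exclusive. The conditional intercept is
#' solved numerically so the marginal composite prevalence at baseline equals
#' `baseline_p` despite the risk-class offsets and random intercepts.
#'
#' @param config a [generator_config()].
#' @return object of class `synthetic_cohort`: list with `practices`
#'   (practice_id, board, list_size, u), `patients` (patient_id, practice_id,
#'   age_at_q0, sex, deprivation_fifth, registered, da, ap, ac), `alpha0`,
#'   `sigma_u`, and the config.
#' @export
build_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(mix_seed(config$seed, 1L))
  mix <- config$indicator_mix

  n_prac <- sum(config$n_practices_per_board)
  if (n_prac < 1) stop("need at least one practice")
  boards <- rep(c("A", "B", "C"), times = config$n_practices_per_board)
  sigma_u <- config$sigma_u %||% sigma_from_icc(config$target_icc, config$baseline_p)
  practices <- data.frame(
    practice_id = sprintf("P%03d", seq_len(n_prac)),
    board = boards,
    list_size = pmax(50L, as.integer(round(rnorm(n_prac, config$list_size_mean,
                                                 config$list_size_sd)))),
    u = rnorm(n_prac, 0, sigma_u)
  )

  n_pat <- sum(practices$list_size)
  practice_of <- rep(practices$practice_id, times = practices$list_size)

  grp <- sample(c("u65", "a65", "a75"), n_pat, replace = TRUE,
                prob = c(mix$f_u65, mix$f_a65, 1 - mix$f_u65 - mix$f_a65))
  age <- integer(n_pat)
  age[grp == "u65"] <- sample(40:64, sum(grp == "u65"), replace = TRUE)
  age[grp == "a65"] <- sample(65:74, sum(grp == "a65"), replace = TRUE)
  age[grp == "a75"] <- pmin(99L, 75L + as.integer(rexp(sum(grp == "a75"), 1 / 6)))

  # chronic risk classes; ac and ap exclusive (three-way draw)
  draw_apac <- function(n) {
    p <- c(none = (1 - mix$q_ap) * (1 - mix$q_ac),
           ap = mix$q_ap * (1 - mix$q_ac), ac = mix$q_ac)
    sample(names(p), n, replace = TRUE, prob = p / sum(p))
  }
  da <- ap <- ac <- logical(n_pat)
  i65p <- which(grp != "u65")
  da[i65p] <- runif(length(i65p)) < mix$q_da
  apac <- draw_apac(length(i65p))
  ap[i65p] <- apac == "ap"
  ac[i65p] <- apac == "ac"
  ac[grp == "u65"] <- TRUE
  # 65-74: require at least one risk factor (rejection redraw)
  repeat {
    need <- which(grp == "a65" & !da & !ap & !ac)
    if (!length(need)) break
    da[need] <- runif(length(need)) < mix$q_da
    apac <- draw_apac(length(need))
    ap[need] <- apac == "ap"
    ac[need] <- apac == "ac"
  }

  dep <- sample(c(1:5, NA), n_pat, replace = TRUE,
                prob = c(0.19, 0.255, 0.175, 0.14, 0.195, 0.045))
  patients <- data.frame(
    patient_id = sprintf("%s_%05d", practice_of,
                         unlist(lapply(practices$list_size, seq_len))),
    practice_id = practice_of,
    age_at_q0 = age,
    sex = sample(c("M", "F"), n_pat, replace = TRUE, prob = c(0.44, 0.56)),
    deprivation_fifth = dep,
    registered = runif(n_pat) >= config$p_unregistered,
    da = da, ap = ap, ac = ac
  )

  # conditional intercept: marginal composite prevalence = baseline_p at t = 0
  off <- trait_offsets(da, ap, ac, mix)
  tab <- table(off)
  alpha0 <- solve_intercept(config$baseline_p, sigma_u,
                            offsets = as.numeric(names(tab)),
                            weights = as.numeric(tab))

  structure(list(practices = practices, patients = patients,
                 alpha0 = alpha0, sigma_u = sigma_u, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$practices), "practices,",
      nrow(x$patients), "at-risk patients\n")
  cat(sprintf("  sigma_u = %.4f (logit scale), intercept = %.4f\n",
              x$sigma_u, x$alpha0))
  invisible(x)
}
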