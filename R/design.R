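#' Cut practices into thirds of baseline high-risk prescribing
#'
#' Ranks practices by baseline composite rate and cuts them into three groups
#' of near-equal size for stratification. Remainder practices go to the lower
#' thirds first; ties are broken by practice id order.
#'
#' @param baselines data.frame with `practice_id` and `baseline_rate`.
#' @return data.frame `practice_id`, `baseline_rate`, `baseline_third`
#'   (integer 1 = lowest prescribing, 3 = highest).
#' @export
assign_thirds <- function(baselines) {
  stopifnot(is.data.frame(baselines),
            all(c("practice_id", "baseline_rate") %in% names(baselines)))
  n <- nrow(baselines)
  if (n == 0L) stop("no practices supplied")
  if (n < 3L) stop("need at least three practices to form thirds")
  if (any(baselines$baseline_rate < 0 | baselines$baseline_rate > 1))
    stop("baseline_rate must be in [0, 1]")
  ord <- order(baselines$baseline_rate, baselines$practice_id)
  base <- n %/% 3L
  rem <- n %% 3L
  sizes <- base + c(rem >= 1L, rem >= 2L, 0L)
  third <- integer(n)
  third[ord] <- rep.int(1:3, sizes)
  out <- baselines[, c("practice_id", "baseline_rate")]
  out$baseline_third <- third
  out
}

#' Stratified randomisation of practices to blinded groups, then arms
#'
#' Two-step allocation mirroring a blinded cluster-trial design: (1) within
#' each stratum (health board x baseline third) practices are permuted by a
#' seeded RNG and dealt to groups G1/G2/G3 in randomly ordered blocks of
#' three, with stratum remainders assigned to the groups with the smallest
#' running totals so that global group sizes differ by at most one; (2) an
#' independently seeded uniform permutation maps the three groups to the three
#' trial arms. `method = "simple"` replaces the blocked dealing with
#' independent uniform group draws per practice.
#'
#' @param baselines data.frame with `practice_id`, `board`, `baseline_rate`
#'   (a `baseline_third` column is honoured if already present).
#' @param seed_group,seed_arm integer seeds for the two independent steps.
#' @param method `"blocked"` (default) or `"simple"`.
#' @return object of class `allocation_scheme`: data.frame with
#'   `practice_id`, `board`, `baseline_third`, `stratum`, `group`, `arm`, plus
#'   attributes `seed_group`, `seed_arm`, `arm_of_group`.
#' @export
randomise_practices <- function(baselines, seed_group, seed_arm,
                                method = c("blocked", "simple")) {
  method <- match.arg(method)
  stopifnot(all(c("practice_id", "board") %in% names(baselines)))
  boards <- sort(unique(baselines$board))
  if (length(boards) > 3L) stop("unknown boards: expected at most three labels")
  if (is.null(baselines$baseline_third)) baselines <- merge(
    baselines, assign_thirds(baselines)[, c("practice_id", "baseline_third")],
    by = "practice_id")
  groups <- c("G1", "G2", "G3")

  df <- baselines[order(baselines$board, baselines$baseline_third,
                        baselines$practice_id), ]
  df$stratum <- paste0(df$board, ":", df$baseline_third)
  df$group <- NA_character_

  set.seed(seed_group)
  totals <- c(G1 = 0L, G2 = 0L, G3 = 0L)
  for (s in unique(df$stratum)) {
    idx <- which(df$stratum == s)
    idx <- idx[sample.int(length(idx))]
    if (method == "simple") {
      g <- groups[sample.int(3L, length(idx), replace = TRUE)]
    } else {
      g <- character(length(idx))
      n_full <- (length(idx) %/% 3L) * 3L
      if (n_full > 0L)
        g[seq_len(n_full)] <- as.vector(vapply(seq_len(n_full / 3L),
                                               function(b) groups[sample.int(3L)],
                                               character(3L)))
      rem <- length(idx) - n_full
      if (rem > 0L) {
        run <- totals + table(factor(g[seq_len(n_full)], levels = groups))
        pick <- names(sort(run + runif(3L) / 2))[seq_len(rem)]  # ties random
        g[n_full + seq_len(rem)] <- pick
      }
    }
    df$group[idx] <- g
    totals <- totals + table(factor(g, levels = groups))
  }

  set.seed(seed_arm)
  arm_of_group <- sample(trial_arms())
  names(arm_of_group) <- groups
  df$arm <- unname(arm_of_group[df$group])

  df <- df[order(df$practice_id),
           c("practice_id", "board", "baseline_third", "stratum", "group", "arm")]
  rownames(df) <- NULL
  structure(df, class = c("allocation_scheme", "data.frame"),
            seed_group = seed_group, seed_arm = seed_arm,
            arm_of_group = arm_of_group)
}

#' Cluster-trial design effect
#'
#' Variance inflation \eqn{1 + (m - 1)\rho} for clusters of mean size `m` and
#' intraclass correlation `icc`.
#'
#' @param m mean cluster size (>= 1).
#' @param icc intraclass correlation in \[0, 1).
#' @return the design effect.
#' @export
design_effect <- function(m, icc) {
  stopifnot(all(m >= 1), all(icc >= 0), all(icc < 1))
  1 + (m - 1) * icc
}

resolve_p2 <- function(p_control, p_intervention, relative_reduction) {
  if (is.null(p_intervention)) {
    if (is.null(relative_reduction))
      stop("give p_intervention or relative_reduction")
    p_intervention <- p_control * (1 - relative_reduction)
  }
  stopifnot(p_control > 0, p_control < 1, p_intervention > 0, p_intervention < 1)
  p_intervention
}

#' Power of a two-arm cluster trial comparing two proportions
#'
#' Normal-approximation power of the two-sided level-`alpha` z test for two
#' proportions with the per-arm effective sample size `k * m / (1 + (m-1)*icc)`
#' (the design-effect adjusted formula):
#' \deqn{\Phi\left(|p_1 - p_2|\sqrt{n_\mathrm{eff} /(p_1 q_1 + p_2 q_2)} -
#'   z_{1 - \alpha/2}\right).}
#'
#' @param p_control control-arm proportion.
#' @param p_intervention intervention-arm proportion; alternatively give
#'   `relative_reduction`.
#' @param relative_reduction relative reduction from `p_control` (e.g. 0.25).
#' @param m mean cluster size.
#' @param icc intraclass correlation.
#' @param k clusters per arm.
#' @param alpha two-sided significance level of the comparison.
#' @return power as a fraction in (0, 1).
#' @export
power_two_proportions_cluster <- function(p_control, p_intervention = NULL,
                                          relative_reduction = NULL,
                                          m, icc, k, alpha = 0.05) {
  p2 <- resolve_p2(p_control, p_intervention, relative_reduction)
  stopifnot(k >= 2, alpha > 0, alpha < 1)
  n_eff <- k * m / design_effect(m, icc)
  delta <- abs(p_control - p2)
  v <- p_control * (1 - p_control) + p2 * (1 - p2)
  pnorm(delta * sqrt(n_eff / v) - qnorm(1 - alpha / 2))
}

#' Smallest number of clusters per arm reaching a target power
#'
#' @inheritParams power_two_proportions_cluster
#' @param target_power required power in (0, 1).
#' @return integer `k`, the smallest clusters-per-arm count with
#'   `power_two_proportions_cluster(k) >= target_power`.
#' @export
clusters_required <- function(p_control, p_intervention = NULL,
                              relative_reduction = NULL,
                              m, icc, alpha = 0.05, target_power = 0.9) {
  if (target_power >= 1 || target_power <= 0) stop("target_power must be in (0, 1)")
  p2 <- resolve_p2(p_control, p_intervention, relative_reduction)
  if (p2 == p_control) stop("no effect: power target unattainable")
  pw <- function(k) power_two_proportions_cluster(p_control, p2, m = m,
                                                  icc = icc, k = k, alpha = alpha)
  k <- 2L
  while (pw(k) < target_power) {
    k <- k + 1L
    if (k > 1e7) stop("target power unattainable within 1e7 clusters")
  }
  k
}

#' Monte-Carlo check of cluster-trial power
#'
#' Simulates beta-binomial cluster outcomes matching `(p, icc)` in each arm
#' (cluster probabilities `Beta` with mean `p` and intraclass correlation
#' `icc`; `icc = 0` gives fixed `p`), analyses each replicate, and returns the
#' rejection fraction with a binomial confidence interval. Analysis is either
#' a two-sample t test on cluster-level proportions (default) or a
#' quasibinomial GLM Wald test on aggregate counts.
#'
#' @inheritParams power_two_proportions_cluster
#' @param n_reps number of simulated trials (>= 100).
#' @param seed integer seed.
#' @param analysis `"cluster_ttest"` or `"glm"`.
#' @return list with `power`, `ci_low`, `ci_high`, `n_reps`.
#' @export
simulate_power <- function(p_control, p_intervention = NULL,
                           relative_reduction = NULL,
                           m, icc, k, alpha = 0.05, n_reps = 500, seed = 1L,
                           analysis = c("cluster_ttest", "glm")) {
  analysis <- match.arg(analysis)
  if (n_reps < 100) stop("n_reps must be at least 100")
  p2 <- resolve_p2(p_control, p_intervention, relative_reduction)
  set.seed(mix_seed(seed, 29L))
  draw_arm <- function(p) {
    if (icc == 0) pc <- rep(p, k)
    else {
      ab <- 1 / icc - 1
      pc <- rbeta(k, p * ab, (1 - p) * ab)
    }
    rbinom(k, m, pc)
  }
  rej <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    y1 <- draw_arm(p_control)
    y2 <- draw_arm(p2)
    if (analysis == "cluster_ttest") {
      pv <- t.test(y1 / m, y2 / m)$p.value
    } else {
      d <- data.frame(num = c(y1, y2), den = m,
                      arm = rep(0:1, each = k))
      pv <- summary(glm(cbind(num, den - num) ~ arm,
                        family = stats::quasibinomial, data = d))$coefficients["arm", 4L]
    }
    rej[r] <- pv < alpha
  }
  ci <- prevalence_with_ci(sum(rej), n_reps)
  list(power = mean(rej), ci_low = ci$ci_low, ci_high = ci$ci_high,
       n_reps = n_reps)
}
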