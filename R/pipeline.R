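practice_baselines <- function(counts, practices, baseline_quarter = 0L,
                               window = 4L) {
  qs <- seq.int(baseline_quarter - window + 1L, baseline_quarter)
  cc <- counts[counts$indicator == "composite" & counts$quarter %in% qs, ]
  agg <- stats::aggregate(cbind(numerator, denominator) ~ practice_id,
                          data = cc, FUN = sum)
  agg$baseline_rate <- agg$numerator / pmax(agg$denominator, 1)
  merge(agg[, c("practice_id", "baseline_rate")],
        practices[, c("practice_id", "board")], by = "practice_id")
}

fit_endpoint_model <- function(counts, allocation, quarter, indicator,
                               nAGQ = 15L) {
  d <- counts[counts$quarter == quarter & counts$indicator == indicator, ]
  d <- merge(d, as.data.frame(allocation)[, c("practice_id", "arm", "board",
                                              "baseline_third")],
             by = "practice_id")
  d <- d[d$denominator > 0, ]
  d$arm <- factor(d$arm, levels = intersect(trial_arms(), unique(d$arm)))
  d$board <- factor(d$board)
  d$baseline_third <- factor(d$baseline_third)
  rhs <- "arm"
  if (nlevels(d$board) > 1L) rhs <- c(rhs, "board")
  if (nlevels(d$baseline_third) > 1L) rhs <- c(rhs, "baseline_third")
  form <- stats::as.formula(paste(
    "cbind(numerator, denominator - numerator) ~", paste(rhs, collapse = " + ")))
  fit_mixed_logit(form, d, cluster = "practice_id", nAGQ = nAGQ)
}

fmt_counts <- function(num, den) {
  sprintf("%d/%d (%.1f)", num, den, 100 * num / pmax(den, 1))
}

#' Run the full simulated trial pipeline
#'
#' End-to-end orchestration: generate the cohort, simulate pre-intervention
#' quarters, measure indicators, stratify and randomise practices (board x
#' baseline third, blinded group-to-arm step), simulate post-intervention
#' quarters with the configured arm effects, then fit the two estimation
#' procedures -- the random-intercept logistic comparison of arms in the
#' final quarter (adjusted for the stratification variables) and the
#' segmented GEE change-point model over the full panel -- and assemble a
#' three-table report.
#'
#' @param config a [generator_config()].
#' @param seed_group,seed_arm seeds for the two randomisation steps; derived
#'   from `config$seed` when `NULL`.
#' @param lost_practice_ids practices lost to follow-up (merged/split):
#'   retained in the allocation audit trail, excluded from analysis.
#' @param nAGQ quadrature points for the endpoint model.
#' @param working_correlation working correlation for the change-point GEE.
#' @param secondary also fit the endpoint model for each individual indicator
#'   (default `TRUE`).
#' @return object of class `trial_report`: list with `table1`, `table2`,
#'   `table3`, `allocation`, `counts`, `endpoint_fits`, `changepoint_fit`,
#'   `provenance`.
#' @export
run_trial <- function(config, seed_group = NULL, seed_arm = NULL,
                      lost_practice_ids = NULL, nAGQ = 15L,
                      working_correlation = "unstructured",
                      secondary = TRUE) {
  stopifnot(inherits(config, "generator_config"))
  seed_group <- seed_group %||% mix_seed(config$seed, 11L)
  seed_arm <- seed_arm %||% mix_seed(config$seed, 12L)

  cohort <- build_cohort(config)
  window <- study_quarters(config)
  pre_q <- window[window <= 0L]
  post_q <- window[window > 0L]

  events_pre <- simulate_panel(cohort, allocation = NULL, quarters = pre_q)
  counts_pre <- measure_panel(cohort$patients, events_pre, quarters = pre_q)

  baselines <- practice_baselines(counts_pre, cohort$practices,
                                  window = min(4L, config$n_quarters_pre))
  allocation <- randomise_practices(baselines, seed_group, seed_arm)

  events_post <- simulate_panel(cohort, allocation = allocation,
                                quarters = post_q)
  counts_post <- measure_panel(cohort$patients, events_post, quarters = post_q)
  counts <- rbind(counts_pre, counts_post)

  if (!is.null(lost_practice_ids)) {
    unknown <- setdiff(lost_practice_ids, allocation$practice_id)
    if (length(unknown)) stop("unknown lost practice id(s)")
  }
  allocation$analysed <- !(allocation$practice_id %in% lost_practice_ids)
  counts_an <- counts[counts$practice_id %in%
                        allocation$practice_id[allocation$analysed], ]

  # --- Table 1: baseline characteristics and performance, by arm
  arm_of <- allocation$arm[match(cohort$practices$practice_id,
                                 allocation$practice_id)]
  base_q <- counts_an[counts_an$quarter == 0L, ]
  base_q$arm <- allocation$arm[match(base_q$practice_id, allocation$practice_id)]
  arms <- trial_arms()
  t1_rows <- list(data.frame(
    row = "practices_n",
    t(vapply(arms, function(a)
      as.character(sum(allocation$arm == a & allocation$analysed)), ""))),
    data.frame(row = "mean_list_size",
               t(vapply(arms, function(a)
                 sprintf("%.0f", mean(cohort$practices$list_size[arm_of == a])),
                 ""))))
  comp0 <- base_q[base_q$indicator == "composite", ]
  t1_rows <- c(t1_rows, list(data.frame(
    row = "patients_at_risk",
    t(vapply(arms, function(a)
      as.character(sum(comp0$denominator[comp0$arm == a])), "")))))
  for (ind in indicator_names()) {
    sub <- base_q[base_q$indicator == ind, ]
    t1_rows <- c(t1_rows, list(data.frame(
      row = paste0("baseline_", ind),
      t(vapply(arms, function(a)
        fmt_counts(sum(sub$numerator[sub$arm == a]),
                   sum(sub$denominator[sub$arm == a])), "")))))
  }
  table1 <- do.call(rbind, t1_rows)
  names(table1) <- c("row", arms)
  rownames(table1) <- NULL

  # --- Endpoint models (final quarter)
  final_q <- max(window)
  outcome_set <- if (secondary) indicator_names() else "composite"
  endpoint_fits <- lapply(stats::setNames(outcome_set, outcome_set),
                          function(ind)
                            fit_endpoint_model(counts_an, allocation, final_q,
                                               ind, nAGQ = nAGQ))
  fin <- counts_an[counts_an$quarter == final_q, ]
  fin$arm <- allocation$arm[match(fin$practice_id, allocation$practice_id)]
  or_cell <- function(fit, term) {
    o <- or_with_ci(fit, term)
    sprintf("%.2f (%.2f to %.2f); P=%.3g", o$or, o$ci_low, o$ci_high, o$p)
  }
  table2 <- do.call(rbind, lapply(outcome_set, function(ind) {
    sub <- fin[fin$indicator == ind, ]
    fit <- endpoint_fits[[ind]]
    data.frame(
      outcome = ind,
      usual_care = fmt_counts(sum(sub$numerator[sub$arm == "usual_care"]),
                              sum(sub$denominator[sub$arm == "usual_care"])),
      feedback = fmt_counts(sum(sub$numerator[sub$arm == "feedback"]),
                            sum(sub$denominator[sub$arm == "feedback"])),
      feedback_bcc = fmt_counts(sum(sub$numerator[sub$arm == "feedback_bcc"]),
                                sum(sub$denominator[sub$arm == "feedback_bcc"])),
      or_feedback_vs_usual = or_cell(fit, "armfeedback"),
      or_feedback_bcc_vs_usual = or_cell(fit, "armfeedback_bcc")
    )
  }))
  rownames(table2) <- NULL

  # --- Change-point GEE over the full panel
  panel <- build_panel(counts_an, allocation)
  cp_fit <- fit_gee_changepoint(panel, working_correlation = working_correlation)
  table3 <- cp_fit$or_table

  provenance <- list(
    package_version = as.character(packageVersion("rxsafetrial")),
    seed = config$seed, seed_group = seed_group, seed_arm = seed_arm,
    config_hash = hash_config(config),
    n_practices = nrow(cohort$practices),
    n_practices_analysed = sum(allocation$analysed),
    n_patients = nrow(cohort$patients),
    quarters = range(window)
  )

  structure(list(table1 = table1, table2 = table2, table3 = table3,
                 allocation = allocation, counts = counts,
                 endpoint_fits = endpoint_fits, changepoint_fit = cp_fit,
                 provenance = provenance),
            class = "trial_report")
}

#' @export
print.trial_report <- function(x, ...) {
  cat("== Simulated prescribing-safety trial report ==\n")
  cat("Config hash:", x$provenance$config_hash, "\n\n")
  cat("-- Table 1: baseline --\n"); print(x$table1, row.names = FALSE)
  cat("\n-- Table 2: endpoint comparison --\n"); print(x$table2, row.names = FALSE)
  cat("\n-- Table 3: change-point model --\n")
  tab <- x$table3
  tab[-1] <- lapply(tab[-1], function(v) signif(v, 3))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Write a trial report to delimited text files
#'
#' Writes `table1.tsv`, `table2.tsv`, `table3.tsv`, `allocation.tsv`,
#' `counts.tsv` and `provenance.json` into `dir`. Output is deterministic
#' given the report.
#'
#' @param report a [run_trial()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "trial_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, f) write.table(df, file.path(dir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
  wt(report$table1, "table1.tsv")
  wt(report$table2, "table2.tsv")
  wt(format(report$table3, digits = 10), "table3.tsv")
  wt(as.data.frame(report$allocation), "allocation.tsv")
  wt(report$counts, "counts.tsv")
  jsonlite::write_json(report$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Lower-quartile benchmark rates across practices
#'
#' Per-indicator "best in class" benchmark: the lower quartile (linear
#' interpolation, practices weighted equally) of practice-level rates pooled
#' over the benchmark window -- by default the four quarters ending at
#' baseline, i.e. the year before feedback starts.
#'
#' @param counts practice-quarter counts (long format).
#' @param quarters quarters to pool (default `-3:0`).
#' @return named numeric vector of benchmark rates, one per indicator.
#' @export
benchmark_rates <- function(counts, quarters = -3:0) {
  cc <- counts[counts$quarter %in% quarters, ]
  if (!nrow(cc)) stop("no counts in the benchmark window")
  inds <- intersect(indicator_names(), unique(cc$indicator))
  vapply(stats::setNames(inds, inds), function(ind) {
    sub <- cc[cc$indicator == ind, ]
    agg <- stats::aggregate(cbind(numerator, denominator) ~ practice_id,
                            data = sub, FUN = sum)
    rates <- agg$numerator / pmax(agg$denominator, 1)
    unname(quantile(rates, 0.25, type = 7))
  }, 0)
}

#' Feedback summary for one practice
#'
#' The quarterly rate series for each indicator with the benchmark attached,
#' flagging indicators whose latest rate exceeds the benchmark. A practice
#' exactly at the benchmark is not flagged (strict `>`).
#'
#' @param practice_counts counts for a single practice (long format).
#' @param benchmark named benchmark rates as from [benchmark_rates()], or a
#'   single number recycled across indicators.
#' @return data.frame with one row per indicator x quarter: `indicator`,
#'   `quarter`, `rate`, `benchmark`, `above_benchmark` (flag refers to the
#'   row's own quarter).
#' @export
render_feedback <- function(practice_counts, benchmark) {
  if (!nrow(practice_counts)) stop("no counts supplied for this practice")
  if (length(unique(practice_counts$practice_id)) > 1L)
    stop("counts for a single practice expected")
  inds <- intersect(indicator_names(), unique(practice_counts$indicator))
  if (length(benchmark) == 1L && is.null(names(benchmark)))
    benchmark <- stats::setNames(rep(benchmark, length(inds)), inds)
  out <- practice_counts[practice_counts$indicator %in% inds,
                         c("indicator", "quarter", "numerator", "denominator")]
  out$rate <- ifelse(out$denominator > 0, out$numerator / out$denominator, NA)
  out$benchmark <- unname(benchmark[out$indicator])
  out$above_benchmark <- !is.na(out$rate) & out$rate > out$benchmark
  out <- out[order(match(out$indicator, indicator_names()), out$quarter), ]
  rownames(out) <- NULL
  out
}

#' Canonical hash of a generator configuration
#'
#' md5 of the configuration rendered as canonical (name-sorted) JSON; changes
#' if and only if some configuration field changes.
#'
#' @param config a [generator_config()] (or any list).
#' @return md5 hex string.
#' @export
config_hash <- function(config) hash_config(config)
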