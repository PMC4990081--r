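#' Assemble the practice-quarter analysis panel
#'
#' Joins composite practice-quarter counts to the allocation, centres time at
#' the baseline (last pre-intervention) quarter, scales it to years, and adds
#' the post-intervention dummy. Every practice must contribute the full
#' quarter grid unless `allow_gaps = TRUE`.
#'
#' @param counts practice-quarter counts as from [measure_panel()] (long
#'   format with an `indicator` column) or already-composite counts with
#'   `numerator`/`denominator` columns.
#' @param allocation an `allocation_scheme` (or data.frame with
#'   `practice_id`, `arm`, and optionally `board`, `baseline_third`).
#' @param baseline_quarter quarter index of the last pre-intervention
#'   quarter (default 0).
#' @param indicator which indicator to analyse (default `"composite"`).
#' @param allow_gaps keep practices with missing quarters instead of erroring.
#' @return data.frame with `practice_id`, `quarter`, `t` (years), `post`,
#'   `arm`, `numerator`, `denominator` and any stratification columns,
#'   canonically sorted by practice then quarter.
#' @export
build_panel <- function(counts, allocation, baseline_quarter = 0L,
                        indicator = "composite", allow_gaps = FALSE) {
  stopifnot(all(c("practice_id", "quarter") %in% names(counts)))
  if ("indicator" %in% names(counts))
    counts <- counts[counts$indicator == indicator, ]
  if (!nrow(counts)) stop("no rows for indicator ", indicator)
  alloc <- as.data.frame(allocation)
  keep <- intersect(c("practice_id", "arm", "board", "baseline_third"),
                    names(alloc))
  if (!all(c("practice_id", "arm") %in% keep))
    stop("allocation needs practice_id and arm")
  panel <- merge(counts[, c("practice_id", "quarter", "numerator", "denominator")],
                 alloc[, keep], by = "practice_id")
  if (!nrow(panel)) stop("allocation does not match any practice in counts")

  grid <- sort(unique(panel$quarter))
  tab <- table(panel$practice_id)
  if (!allow_gaps && any(tab != length(grid)))
    stop("practice(s) with missing quarters: ",
         paste(utils::head(names(tab)[tab != length(grid)], 5), collapse = ", "),
         " (use allow_gaps = TRUE to keep them)")
  panel$t <- (panel$quarter - baseline_quarter) / 4
  panel$post <- as.integer(panel$quarter > baseline_quarter)
  panel$arm <- factor(panel$arm, levels = intersect(trial_arms(),
                                                    unique(panel$arm)))
  panel <- panel[order(panel$practice_id, panel$quarter), ]
  rownames(panel) <- NULL
  panel
}

# Internal IRLS solver for binomial-proportion GEE with denominator weights.
# X: design; y: proportions; w: denominators; id: cluster factor; time:
# within-cluster position (1..T) for the unstructured estimator.
gee_irls <- function(X, y, w, id, time, corstr, maxit = 100L, tol = 1e-8) {
  id <- factor(id, levels = unique(id))
  cl_rows <- split(seq_along(y), id)
  K <- length(cl_rows)
  p <- ncol(X)
  Tmax <- max(lengths(cl_rows))
  balanced <- all(lengths(cl_rows) == Tmax)

  if (corstr == "unstructured" && !balanced)
    stop("unstructured working correlation requires a balanced panel")

  beta <- glm.fit(X, cbind(round(y * w), round((1 - y) * w)),
                  family = binomial())$coefficients
  R <- diag(Tmax)
  alpha <- 0
  converged <- FALSE

  for (iter in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- expit(eta)
    A <- mu * (1 - mu)
    S <- sqrt(A / w)              # sd of the proportion y_i
    e <- (y - mu) / S             # Pearson residuals
    phi <- sum(e^2) / (length(y) - p)

    if (corstr == "exchangeable") {
      num <- 0; den <- 0
      for (rows in cl_rows) {
        er <- e[rows]
        num <- num + (sum(er)^2 - sum(er^2))
        den <- den + length(er) * (length(er) - 1L)
      }
      alpha <- num / (phi * max(den - p, 1))
      alpha <- min(max(alpha, -0.99 / (Tmax - 1) + 1e-6), 0.99)
      R <- matrix(alpha, Tmax, Tmax); diag(R) <- 1
    } else if (corstr == "unstructured") {
      E <- matrix(0, K, Tmax)
      for (j in seq_len(K)) E[j, time[cl_rows[[j]]]] <- e[cl_rows[[j]]]
      R <- crossprod(E) / (phi * max(K - p, 1))
      R <- stats::cov2cor(R)
      ev <- eigen(R, symmetric = TRUE)
      if (min(ev$values) < 1e-6) {   # project to a positive-definite correlation
        R <- ev$vectors %*% diag(pmax(ev$values, 1e-6)) %*% t(ev$vectors)
        R <- stats::cov2cor(R)
      }
    }

    U <- X * sqrt(A * w)          # D' V^{-1/2} rows: (A/S) x = sqrt(A w) x
    B <- matrix(0, p, p)
    g <- numeric(p)
    for (j in seq_len(K)) {
      rows <- cl_rows[[j]]
      Rj <- if (corstr == "independence") diag(length(rows))
            else R[time[rows], time[rows], drop = FALSE]
      Ri <- solve(Rj)
      Uj <- U[rows, , drop = FALSE]
      B <- B + crossprod(Uj, Ri %*% Uj)
      g <- g + crossprod(Uj, Ri %*% e[rows])
    }
    step <- solve(B, g)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }

  # final quantities at the solution
  eta <- drop(X %*% beta)
  mu <- expit(eta)
  A <- mu * (1 - mu)
  S <- sqrt(A / w)
  e <- (y - mu) / S
  phi <- sum(e^2) / (length(y) - p)
  U <- X * sqrt(A * w)
  B <- matrix(0, p, p)
  M <- matrix(0, p, p)
  g <- numeric(p)
  for (j in seq_len(K)) {
    rows <- cl_rows[[j]]
    Rj <- if (corstr == "independence") diag(length(rows))
          else R[time[rows], time[rows], drop = FALSE]
    Ri <- solve(Rj)
    Uj <- U[rows, , drop = FALSE]
    sj <- drop(crossprod(Uj, Ri %*% e[rows]))
    B <- B + crossprod(Uj, Ri %*% Uj)
    M <- M + tcrossprod(sj)
    g <- g + sj
  }
  Binv <- solve(B)
  list(beta = beta, vcov_sandwich = Binv %*% M %*% Binv,
       vcov_model = Binv * phi, working_correlation = R, alpha = alpha,
       phi = phi, converged = converged, iterations = iter,
       score_norm = sqrt(sum(g^2)), n_clusters = K)
}

#' Binomial GEE with a working correlation and sandwich variances
#'
#' Solves the generalised estimating equations for grouped binomial data
#' (logit link, proportion response with denominator weights) by iteratively
#' reweighted least squares with moment updates of the working correlation,
#' and returns the cluster-robust sandwich covariance
#' \eqn{B^{-1} M B^{-1}} (bread = model information under the working
#' correlation, meat = empirical outer product of cluster scores).
#'
#' @param formula model formula with `cbind(successes, failures)` response.
#' @param data data.frame, rows ordered within cluster.
#' @param id name of the cluster column.
#' @param corstr working correlation: `"independence"`, `"exchangeable"`, or
#'   `"unstructured"` (needs a balanced panel).
#' @param time optional name of an integer column giving within-cluster
#'   occasion (1-based); defaults to row order within cluster.
#' @param maxit,tol IRLS controls (`max |step| < tol`).
#' @return list with `beta`, `vcov_sandwich`, `vcov_model`,
#'   `working_correlation`, `phi`, `converged`, `iterations`, `score_norm`.
#' @export
gee_binomial <- function(formula, data, id,
                         corstr = c("independence", "exchangeable",
                                    "unstructured"),
                         time = NULL, maxit = 100L, tol = 1e-8) {
  corstr <- match.arg(corstr)
  stopifnot(id %in% names(data))
  mf <- model.frame(formula, data)
  X <- model.matrix(formula, mf)
  Y <- model.response(mf)
  if (!is.matrix(Y) || ncol(Y) != 2L)
    stop("response must be cbind(successes, failures)")
  n <- Y[, 1L] + Y[, 2L]
  if (any(n <= 0)) stop("each row needs a positive denominator")
  idv <- data[[id]]
  tv <- if (is.null(time)) stats::ave(seq_along(idv), idv, FUN = seq_along)
        else data[[time]]
  fit <- gee_irls(X, Y[, 1L] / n, n, idv, as.integer(tv), corstr, maxit, tol)
  names(fit$beta) <- colnames(X)
  dimnames(fit$vcov_sandwich) <- dimnames(fit$vcov_model) <-
    list(colnames(X), colnames(X))
  fit
}

#' Segmented (change-point) GEE for the quarterly prescribing panel
#'
#' Fits the marginal binomial model
#' \deqn{\mathrm{logit}\, p_{jt} = \alpha + \gamma t +
#'   \sum_a \mathbf{1}[\mathrm{arm}_j = a]\, \mathrm{post}_t
#'   (\delta_a + \theta_a t) + \text{board} + \text{baseline third}}
#' with a common pre-intervention trend \eqn{\gamma} (per year), a per-arm
#' immediate level shift \eqn{\delta_a} and per-arm slope change
#' \eqn{\theta_a}, using [gee_binomial()] with the requested working
#' correlation and cluster-robust sandwich variances. Reported odds ratios:
#' the pre-intervention trend `exp(gamma)` per year, each arm's slope change
#' `exp(theta_a)` per year, and each arm's step as the model-implied contrast
#' between the first post-intervention quarter and the baseline quarter net
#' of the secular trend, `exp(delta_a + theta_a * dt)` with `dt` the quarter
#' spacing in years (0.25).
#'
#' @param panel a [build_panel()] data.frame (or [simulate_counts_panel()]
#'   output); stratification columns `board`/`baseline_third` are adjusted
#'   for when present.
#' @param working_correlation `"unstructured"` (default; falls back to
#'   exchangeable with a warning when fewer than 30 practices are available),
#'   `"exchangeable"`, or `"independence"`.
#' @param min_clusters_unstructured fallback threshold (default 30).
#' @return object of class `gee_changepoint_fit`: list with `beta`,
#'   `vcov_sandwich`, `working_correlation`, `or_table` (terms `pre_trend`,
#'   `step_<arm>`, `slope_change_<arm>`), `corstr`, `converged`,
#'   `score_norm`, `n_clusters`, `iterations`.
#' @export
fit_gee_changepoint <- function(panel,
                                working_correlation = c("unstructured",
                                                        "exchangeable",
                                                        "independence"),
                                min_clusters_unstructured = 30L) {
  corstr <- match.arg(working_correlation)
  need <- c("practice_id", "t", "post", "arm", "numerator", "denominator")
  stopifnot(all(need %in% names(panel)))
  panel <- panel[order(panel$practice_id, panel$t), ]
  panel$arm <- droplevels(factor(panel$arm,
                                 levels = intersect(trial_arms(),
                                                    unique(as.character(panel$arm)))))
  K <- length(unique(panel$practice_id))
  if (corstr == "unstructured" && K < min_clusters_unstructured) {
    warning("fewer than ", min_clusters_unstructured,
            " practices: falling back to exchangeable working correlation")
    corstr <- "exchangeable"
  }

  adjust <- intersect(c("board", "baseline_third"), names(panel))
  for (a in adjust) panel[[a]] <- factor(panel[[a]])
  arms <- levels(panel$arm)
  # per-arm step and slope-change columns
  for (a in arms) {
    ind <- as.numeric(panel$arm == a) * panel$post
    panel[[paste0("step_", a)]] <- ind
    panel[[paste0("slope_", a)]] <- ind * panel$t
  }
  rhs <- c("t", adjust, paste0("step_", arms), paste0("slope_", arms))
  form <- stats::as.formula(paste(
    "cbind(numerator, denominator - numerator) ~", paste(rhs, collapse = " + ")))

  panel$.occ <- stats::ave(seq_len(nrow(panel)), panel$practice_id, FUN = seq_along)
  fit <- gee_binomial(form, panel, id = "practice_id", corstr = corstr,
                      time = ".occ")
  if (!fit$converged) warning("GEE did not converge")

  V <- fit$vcov_sandwich
  beta <- fit$beta
  dt <- min(panel$t[panel$post == 1])
  z975 <- qnorm(0.975)
  row_for <- function(term, contrast) {
    est <- sum(contrast * beta)
    se <- sqrt(drop(t(contrast) %*% V %*% contrast))
    data.frame(term = term, estimate = est, se = se, or = exp(est),
               ci_low = exp(est - z975 * se), ci_high = exp(est + z975 * se),
               p = 2 * pnorm(-abs(est / se)))
  }
  unit <- function(name) { v <- numeric(length(beta)); v[names(beta) == name] <- 1; v }
  rows <- list(row_for("pre_trend", unit("t")))
  for (a in arms) {
    cstep <- unit(paste0("step_", a)) + dt * unit(paste0("slope_", a))
    rows <- c(rows, list(row_for(paste0("step_", a), cstep),
                         row_for(paste0("slope_change_", a),
                                 unit(paste0("slope_", a)))))
  }
  or_table <- do.call(rbind, rows)
  rownames(or_table) <- NULL

  structure(list(beta = beta, vcov_sandwich = V, vcov_model = fit$vcov_model,
                 working_correlation = fit$working_correlation,
                 phi = fit$phi, corstr = corstr, converged = fit$converged,
                 iterations = fit$iterations, score_norm = fit$score_norm,
                 n_clusters = fit$n_clusters, or_table = or_table,
                 step_dt = dt),
            class = "gee_changepoint_fit")
}

#' Cluster-robust sandwich covariance of a GEE fit
#'
#' @param fit a [fit_gee_changepoint()] or [gee_binomial()] result.
#' @return the sandwich covariance matrix of the coefficients.
#' @export
sandwich_cov <- function(fit) {
  V <- fit$vcov_sandwich
  if (is.null(V)) stop("fit carries no sandwich covariance")
  V
}

#' @export
print.gee_changepoint_fit <- function(x, ...) {
  cat("Binomial GEE change-point fit (", x$corstr,
      " working correlation, ", x$n_clusters, " practices)\n", sep = "")
  if (!x$converged) cat("  [NOT CONVERGED]\n")
  tab <- x$or_table
  tab[-1] <- lapply(tab[-1], function(v) signif(v, 4))
  print(tab, row.names = FALSE)
  invisible(x)
}
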