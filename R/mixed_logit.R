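# Internal: per-cluster adaptive GH marginal log-likelihood machinery.
# Data are stored as (X, y, n, cluster index) with binomial rows; the
# integrand for cluster j is
#   h_j(z) = sum_i [y_i eta_i - n_i log(1 + e^eta_i)] - z^2/2 - log sqrt(2*pi),
#   eta_i = x_i' beta + sigma * z,
# and the marginal contribution is log INT exp(h_j(z)) dz, evaluated by
# Gauss-Hermite quadrature recentred at the mode with curvature scaling.
agq_loglik_machine <- function(X, y, n, cluster) {
  cluster <- as.integer(factor(cluster, levels = unique(cluster)))
  J <- max(cluster)
  lchoose_const <- sum(lchoose(n, y))
  rs <- function(v) rowsum(v, cluster, reorder = FALSE)[, 1L]

  function(beta, sigma, nAGQ = 15L) {
    gh <- gauss_hermite(nAGQ)
    lw <- log(gh$weights) + gh$nodes^2
    eta0 <- drop(X %*% beta)
    # Newton for per-cluster modes (vectorised across clusters)
    z <- numeric(J)
    for (it in 1:50) {
      eta <- eta0 + sigma * z[cluster]
      p <- expit(eta)
      g <- sigma * rs(y - n * p) - z
      H <- -sigma^2 * rs(n * p * (1 - p)) - 1
      step <- g / H
      step <- pmin(pmax(step, -4), 4)
      z <- z - step
      if (max(abs(step)) < 1e-11) break
    }
    eta <- eta0 + sigma * z[cluster]
    p <- expit(eta)
    H <- -sigma^2 * rs(n * p * (1 - p)) - 1
    tau <- 1 / sqrt(-H)

    h_at <- function(zz) {
      eta <- eta0 + sigma * zz[cluster]
      rs(y * eta - n * log1p(exp(eta))) - zz^2 / 2 - log(sqrt(2 * pi))
    }
    terms <- matrix(0, J, nAGQ)
    for (k in seq_len(nAGQ))
      terms[, k] <- lw[k] + h_at(z + sqrt(2) * tau * gh$nodes[k])
    mx <- apply(terms, 1L, max)
    ll_j <- mx + log(rowSums(exp(terms - mx))) + log(sqrt(2) * tau)
    sum(ll_j) + lchoose_const
  }
}

parse_binomial_response <- function(mf) {
  Y <- model.response(mf)
  if (is.matrix(Y)) {
    if (ncol(Y) != 2L) stop("matrix response must have two columns (successes, failures)")
    list(y = Y[, 1L], n = Y[, 1L] + Y[, 2L])
  } else {
    if (!all(Y %in% c(0, 1))) stop("vector response must be binary 0/1")
    list(y = as.numeric(Y), n = rep(1, length(Y)))
  }
}

#' Marginal log-likelihood of the random-intercept logistic model
#'
#' Evaluates the adaptive Gauss-Hermite approximation to the marginal
#' log-likelihood at user-supplied parameter values. Useful for checking
#' the integration against brute-force numerical quadrature.
#'
#' @param formula binomial model formula (`cbind(successes, failures) ~ ...`
#'   or binary response).
#' @param data data.frame.
#' @param cluster name of the clustering column in `data`.
#' @param beta fixed-effect coefficients (design-matrix order).
#' @param sigma random-intercept SD (>= 0).
#' @param nAGQ number of quadrature points.
#' @return the marginal log-likelihood (including binomial constants).
#' @export
mixed_logit_loglik <- function(formula, data, cluster, beta, sigma, nAGQ = 15L) {
  mf <- model.frame(formula, data)
  X <- model.matrix(formula, mf)
  r <- parse_binomial_response(mf)
  machine <- agq_loglik_machine(X, r$y, r$n, data[[cluster]])
  machine(beta, sigma, nAGQ)
}

#' Random-intercept logistic regression by adaptive Gauss-Hermite quadrature
#'
#' Maximum-likelihood fit of the two-level logistic model
#' \deqn{\mathrm{logit}\, P(y_{ij} = 1 \mid u_j) = x_{ij}'\beta + u_j, \quad
#'   u_j \sim N(0, \sigma_u^2),}
#' integrating the practice-level intercept out of the likelihood with
#' mode-recentred, curvature-scaled Gauss-Hermite quadrature (`nAGQ` points;
#' 1 point is the Laplace approximation). Rows may be binomial counts
#' (`cbind(successes, failures)` response), which is exact when covariates
#' are constant within the aggregated rows. Standard errors are model-based
#' Wald from the numerically differentiated observed information.
#'
#' @param formula model formula; the reference levels of factor covariates
#'   define the baseline (arms should be given with usual care first).
#' @param data data.frame.
#' @param cluster name of the clustering column (e.g. practice id).
#' @param nAGQ quadrature points (default 15).
#' @param tol projected-gradient tolerance passed to the optimiser.
#' @return object of class `mixed_logit_fit`: list with `beta`, `se`,
#'   `sigma_u`, `vcov`, `loglik`, `loglik_init`, `converged`, `or_table`,
#'   `n_clusters`, `n_obs`, `nAGQ`.
#' @export
fit_mixed_logit <- function(formula, data, cluster, nAGQ = 15L, tol = 1e-8) {
  stopifnot(is.character(cluster), cluster %in% names(data))
  mf <- model.frame(formula, data)
  X <- model.matrix(formula, mf)
  r <- parse_binomial_response(mf)
  cl <- data[[cluster]]
  if (length(unique(cl)) < 2L) stop("need at least two clusters")
  if (sum(r$y) == 0 || sum(r$y) == sum(r$n)) stop("outcome is constant")
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")

  machine <- agq_loglik_machine(X, r$y, r$n, cl)
  p <- ncol(X)

  g0 <- glm.fit(X, cbind(r$y, r$n - r$y), family = binomial())
  start <- c(g0$coefficients, 0.3)
  ll_init <- machine(start[1:p], start[p + 1L], nAGQ)

  negll <- function(th) -machine(th[1:p], th[p + 1L], nAGQ)
  opt <- optim(start, negll, method = "L-BFGS-B",
               lower = c(rep(-Inf, p), 0),
               control = list(maxit = 500, factr = 1e4, pgtol = tol),
               hessian = FALSE)
  theta <- opt$par
  beta <- theta[1:p]
  names(beta) <- colnames(X)
  sigma_u <- theta[p + 1L]

  if (any(abs(beta) > 15))
    warning("very large coefficient(s): possible separation")

  # observed information by central differences; if sigma sits on the
  # boundary, differentiate over beta only
  at_boundary <- sigma_u < 1e-4
  idx <- if (at_boundary) seq_len(p) else seq_len(p + 1L)
  hess <- num_hessian(function(th_sub) {
    th <- theta
    th[idx] <- th_sub
    -machine(th[1:p], max(th[p + 1L], 0), nAGQ)
  }, theta[idx])
  vc <- tryCatch(solve(hess), error = function(e) matrix(NA_real_, length(idx), length(idx)))
  vcov_beta <- vc[seq_len(p), seq_len(p), drop = FALSE]
  dimnames(vcov_beta) <- list(names(beta), names(beta))
  se <- sqrt(pmax(diag(vcov_beta), 0))

  z975 <- qnorm(0.975)
  zstat <- beta / se
  or_table <- data.frame(
    term = names(beta),
    estimate = beta,
    se = se,
    or = exp(beta),
    ci_low = exp(beta - z975 * se),
    ci_high = exp(beta + z975 * se),
    p = 2 * pnorm(-abs(zstat)),
    row.names = NULL
  )

  structure(list(beta = beta, se = se, sigma_u = sigma_u, vcov = vcov_beta,
                 loglik = -opt$value, loglik_init = ll_init,
                 converged = opt$convergence == 0L,
                 or_table = or_table, nAGQ = nAGQ,
                 n_clusters = length(unique(cl)), n_obs = sum(r$n),
                 formula = formula, message = opt$message),
            class = "mixed_logit_fit")
}

num_hessian <- function(f, x, eps = 1e-4) {
  p <- length(x)
  h <- pmax(abs(x), 1) * eps
  H <- matrix(0, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) for (j in i:p) {
    ei <- ej <- numeric(p)
    ei[i] <- h[i]; ej[j] <- h[j]
    H[i, j] <- H[j, i] <-
      (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
      (4 * h[i] * h[j])
  }
  H
}

#' Odds ratio with confidence interval for one model term
#'
#' @param fit a [fit_mixed_logit()] or [fit_gee_changepoint()] result.
#' @param term term name as it appears in the fit's `or_table`.
#' @return named list `or`, `ci_low`, `ci_high`, `p`.
#' @export
or_with_ci <- function(fit, term) {
  tab <- fit$or_table
  row <- tab[tab$term == term, ]
  if (nrow(row) != 1L) stop("unknown term: ", term)
  list(or = row$or, ci_low = row$ci_low, ci_high = row$ci_high, p = row$p)
}

#' @export
print.mixed_logit_fit <- function(x, ...) {
  cat("Random-intercept logistic fit (adaptive GHQ,", x$nAGQ, "points)\n")
  cat(sprintf("  %d clusters, %d observations; sigma_u = %.4f; logLik = %.3f%s\n",
              x$n_clusters, x$n_obs, x$sigma_u, x$loglik,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  tab <- x$or_table
  tab[-1] <- lapply(tab[-1], function(v) signif(v, 4))
  print(tab, row.names = FALSE)
  invisible(x)
}
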