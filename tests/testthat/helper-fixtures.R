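# Random patient-quarter profiles for property tests
random_profiles <- function(n, seed = 1, p_class = 0.3) {
  set.seed(seed)
  prof <- data.frame(age = sample(40:95, n, replace = TRUE))
  for (cls in setdiff(drug_classes(), "OTHER"))
    prof[[cls]] <- runif(n) < p_class
  prof
}

# Cluster-level two-arm endpoint data from the random-intercept logistic model
sim_endpoint_data <- function(k, m, p0, arm_or, sigma_u, alpha0 = NULL) {
  alpha0 <- alpha0 %||% solve_intercept(p0, sigma_u)
  arm <- rep(c("usual_care", "feedback"), each = k / 2)
  u <- rnorm(k, 0, sigma_u)
  p <- plogis(alpha0 + log(arm_or) * (arm == "feedback") + u)
  data.frame(practice_id = sprintf("P%03d", seq_len(k)),
             arm = factor(arm, levels = c("usual_care", "feedback")),
             num = rbinom(k, m, p), den = m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# fine-grid trapezoid evaluation of the random-intercept marginal
# log-likelihood -- the independent integration oracle
trapezoid_loglik <- function(data, beta, sigma, xcols, grid_n = 20001) {
  tot <- 0
  for (cl in unique(data$practice_id)) {
    s <- data[data$practice_id == cl, ]
    X <- cbind(1, as.matrix(s[, xcols, drop = FALSE]))
    span <- 10 * max(sigma, 0.1)
    u <- seq(-span, span, length.out = grid_n)
    f <- vapply(u, function(uu) {
      eta <- drop(X %*% beta) + uu
      exp(sum(dbinom(s$num, s$den, plogis(eta), log = TRUE)))
    }, 0)
    g <- f * dnorm(u, 0, sigma)
    tot <- tot + log(sum(g[-1] + g[-length(u)]) / 2 * (u[2] - u[1]))
  }
  tot
}
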