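#' @importFrom stats pnorm qnorm rnorm runif rbinom rbeta rexp glm glm.fit
#'   binomial coef vcov model.matrix model.frame model.response quantile
#'   optim uniroot t.test plogis qlogis
#' @importFrom utils write.table packageVersion
#' @import data.table
NULL

expit <- stats::plogis
logit <- stats::qlogis

#' Gauss-Hermite quadrature nodes and weights
#'
#' Nodes and weights for \eqn{\int f(x) e^{-x^2} dx \approx \sum_k w_k f(g_k)},
#' computed by the Golub-Welsch eigenvalue method on the Jacobi matrix of the
#' Hermite recurrence.
#'
#' @param n number of quadrature points (>= 1).
#' @return list with `nodes` and `weights`, each of length `n`.
#' @export
gauss_hermite <- function(n) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1, n == round(n))
  n <- as.integer(n)
  if (n == 1L) return(list(nodes = 0, weights = sqrt(pi)))
  J <- matrix(0, n, n)
  for (k in seq_len(n - 1L)) J[k, k + 1L] <- J[k + 1L, k] <- sqrt(k / 2)
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = (e$vectors[1L, ]^2 * sqrt(pi))[ord])
}

# deterministic derived seeds, kept below 2^31
mix_seed <- function(seed, offset) {
  s <- (as.double(seed) %% 2147483647) * 69621 + 7919 * (as.double(offset) + 1)
  as.integer(s %% 2147483647L)
}

#' One-way ANOVA intraclass correlation for clustered binary outcomes
#'
#' Moment (ANOVA) estimator of the intraclass correlation on the observed
#' binary scale, from per-cluster numerator/denominator counts. Uses the
#' standard unbalanced-design cluster-size adjustment
#' \eqn{n_0 = (N - \sum n_j^2 / N)/(k - 1)}.
#'
#' @param numerator,denominator integer vectors, one entry per cluster.
#' @return estimated ICC (can be slightly negative in small samples).
#' @export
anova_icc <- function(numerator, denominator) {
  stopifnot(length(numerator) == length(denominator),
            all(denominator > 0), all(numerator >= 0),
            all(numerator <= denominator))
  k <- length(denominator)
  if (k < 2L) stop("need at least two clusters")
  N <- sum(denominator)
  p_j <- numerator / denominator
  p <- sum(numerator) / N
  ssb <- sum(denominator * (p_j - p)^2)
  ssw <- sum(numerator * (1 - p_j))  # sum y - n p_j^2 for binary outcomes
  msb <- ssb / (k - 1)
  msw <- ssw / (N - k)
  n0 <- (N - sum(denominator^2) / N) / (k - 1)
  (msb - msw) / (msb + (n0 - 1) * msw)
}

# canonical md5 of a configuration list (order-stable JSON via sorted names)
hash_config <- function(config) {
  canon <- function(x) {
    if (is.list(x)) {
      nm <- names(x)
      if (!is.null(nm)) x <- x[order(nm)]
      lapply(x, canon)
    } else x
  }
  js <- jsonlite::toJSON(canon(unclass(config)), auto_unbox = TRUE,
                         digits = 15, null = "null", force = TRUE)
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(as.character(js), f)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
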