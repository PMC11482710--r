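# Synthetic data generators used by the simulation studies.

#' Simulate a binary regression dataset
#'
#' Covariates are drawn independently from Uniform(`x_low`, `x_high`)
#' (defaults (-3, 3)), the linear predictor is `x'beta`, and
#' `y ~ Bernoulli(F(eta))` under the given link.
#'
#' @param link a [lomax_link()] (with its `lambda` for the power links).
#' @param beta coefficient vector (intercept first); `length(beta) - 1`
#'   covariates are generated.
#' @param n number of observations.
#' @param x_low,x_high covariate range (defaults -3, 3).
#' @param seed optional integer seed.
#' @return a [binary_dataset()].
#' @examples
#' d <- simulate_binary(lomax_link("rpdlomax", lambda = 2), c(0, 1),
#'                      n = 100, seed = 1)
#' mean(d$y)
#' @export
simulate_binary <- function(link, beta, n, x_low = -3, x_high = 3,
                            seed = NULL) {
  stopifnot(inherits(link, "lomax_link"), n >= 1, length(beta) >= 1)
  if (!is.null(seed)) set.seed(seed)
  p_cov <- length(beta) - 1L
  x <- if (p_cov > 0)
    matrix(stats::runif(n * p_cov, x_low, x_high), n, p_cov,
           dimnames = list(NULL, paste0("x", seq_len(p_cov))))
  else NULL
  eta <- rep(beta[1L], n)
  if (p_cov > 0) eta <- eta + drop(x %*% beta[-1L])
  y <- stats::rbinom(n, 1L, link_prob(eta, link))
  binary_dataset(y, x)
}

#' Simulate from the power Cauchy binary regression model
#'
#' The misspecification-study generator:
#' `p_i = (arctan(x_i'beta)/pi + 1/2)^lambda`, covariates
#' Uniform(`x_low`, `x_high`).
#'
#' @param lam asymmetry parameter of the power Cauchy response, positive.
#' @inheritParams simulate_binary
#' @return a [binary_dataset()].
#' @export
simulate_power_cauchy <- function(lam, beta, n, x_low = -3, x_high = 3,
                                  seed = NULL) {
  .check_lambda(lam)
  stopifnot(n >= 1, length(beta) >= 1)
  if (!is.null(seed)) set.seed(seed)
  p_cov <- length(beta) - 1L
  x <- if (p_cov > 0)
    matrix(stats::runif(n * p_cov, x_low, x_high), n, p_cov,
           dimnames = list(NULL, paste0("x", seq_len(p_cov))))
  else NULL
  eta <- rep(beta[1L], n)
  if (p_cov > 0) eta <- eta + drop(x %*% beta[-1L])
  y <- stats::rbinom(n, 1L, power_cauchy_prob(eta, lam))
  binary_dataset(y, x)
}

#' Expected success rate under a uniform covariate
#'
#' Quadrature oracle for the marginal success probability
#' `E[p(beta0 + beta1 X)]` with `X ~ Uniform(x_low, x_high)` and a single
#' covariate.
#'
#' @param prob_fn function of `(eta, lam)` returning probabilities, e.g.
#'   [power_cauchy_prob()], or of `eta` alone when `lam` is NULL.
#' @param lam asymmetry parameter forwarded to `prob_fn`, or NULL.
#' @param beta length-2 coefficient vector (intercept, slope).
#' @param x_low,x_high covariate range.
#' @return scalar expected success probability.
#' @examples
#' expected_success_rate(power_cauchy_prob, 1, c(0, 1))  # 0.5
#' @export
expected_success_rate <- function(prob_fn, lam = NULL, beta = c(0, 1),
                                  x_low = -3, x_high = 3) {
  stopifnot(length(beta) == 2)
  f <- if (is.null(lam))
    function(x) prob_fn(beta[1] + beta[2] * x)
  else
    function(x) prob_fn(beta[1] + beta[2] * x, lam)
  stats::integrate(f, x_low, x_high, rel.tol = 1e-10,
                   abs.tol = 1e-10)$value / (x_high - x_low)
}
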