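# Bernoulli log-likelihood and log-posterior for a given link.

# resolve the link to use for a given delta draw: for power links the
# asymmetry parameter is exp(delta); other links ignore delta
.link_at <- function(link, delta = NULL) {
  if (link$has_lambda && !is.null(delta))
    lomax_link(link$name, lambda = exp(delta))
  else
    link
}

#' Priors for the regression model
#'
#' Independent Normal(0, `beta_sd`^2) priors on the regression coefficients
#' and a Uniform(`delta_low`, `delta_high`) prior on `delta = log(lambda)`
#' for the power links.  The defaults (sd 10, bounds (-2, 2)) restrict
#' lambda to (e^-2, e^2) = (0.14, 7.39), outside which the skew of the
#' power transforms barely changes.
#'
#' @param beta_sd prior standard deviation of the coefficients (default 10).
#' @param delta_low,delta_high bounds of the uniform prior on delta
#'   (defaults -2, 2).
#' @return object of class `prior_spec`.
#' @export
prior_spec <- function(beta_sd = 10, delta_low = -2, delta_high = 2) {
  stopifnot(beta_sd > 0, delta_low < delta_high)
  structure(list(beta_sd = beta_sd, delta_low = delta_low,
                 delta_high = delta_high),
            class = "prior_spec")
}

#' Implied support of lambda under the delta prior
#'
#' @param priors a [prior_spec()].
#' @return length-2 numeric vector, `exp(c(delta_low, delta_high))`.
#' @examples
#' round(lambda_support(prior_spec()), 2)  # 0.14 7.39
#' @export
lambda_support <- function(priors = prior_spec()) {
  exp(c(priors$delta_low, priors$delta_high))
}

#' Bernoulli log-likelihood
#'
#' \eqn{\sum_i y_i \log p_i + (1 - y_i)\log(1 - p_i)} with
#' \eqn{p_i = F_\lambda(x_i'\beta)}.  For the power links `delta`
#' (= log lambda) sets the asymmetry parameter; for the others it is
#' ignored.
#'
#' @param beta coefficient vector, length `data$k`.
#' @param delta log asymmetry parameter (power links) or NULL.
#' @param data a [binary_dataset()].
#' @param link a [lomax_link()].
#' @return scalar log-likelihood (finite thanks to probability clipping).
#' @export
log_likelihood <- function(beta, delta = NULL, data, link) {
  stopifnot(inherits(data, "binary_dataset"))
  if (length(beta) != data$k)
    stop("`beta` has length ", length(beta), " but the design has ",
         data$k, " columns", call. = FALSE)
  if (data$n == 0L) return(0)
  p <- link_prob(drop(data$X %*% beta), .link_at(link, delta))
  sum(data$y * log(p) + (1 - data$y) * log1p(-p))
}

# pointwise log p(y_i | theta^(s)): S x n matrix, one row per draw
.log_lik_matrix <- function(beta_draws, delta_draws, data, link) {
  S <- nrow(beta_draws)
  out <- matrix(NA_real_, S, data$n)
  eta <- data$X %*% t(beta_draws)            # n x S
  for (s in seq_len(S)) {
    p <- link_prob(eta[, s], .link_at(link, delta_draws[s]))
    out[s, ] <- data$y * log(p) + (1 - data$y) * log1p(-p)
  }
  out
}

#' Log-posterior density (up to a constant)
#'
#' Log-likelihood plus the Normal log-prior on `beta` and the uniform
#' log-prior on `delta`; returns `-Inf` when `delta` falls outside its
#' prior bounds.
#'
#' @inheritParams log_likelihood
#' @param priors a [prior_spec()].
#' @return scalar log-posterior value up to an additive constant.
#' @export
log_posterior <- function(beta, delta = NULL, data, link,
                          priors = prior_spec()) {
  lp <- sum(stats::dnorm(beta, 0, priors$beta_sd, log = TRUE))
  if (link$has_lambda) {
    if (is.null(delta)) delta <- log(link$lambda)
    if (delta <= priors$delta_low || delta >= priors$delta_high)
      return(-Inf)
    lp <- lp - log(priors$delta_high - priors$delta_low)
  }
  lp + log_likelihood(beta, delta, data, link)
}
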