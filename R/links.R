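# Double Lomax distribution and its power / reverse-power transforms.
#
# The double Lomax (DLomax) distribution arises as the ratio of two i.i.d.
# standard Laplace variates: a symmetric, heavy-tailed distribution on the
# real line.  Exponentiating its cdf G by lambda > 0 gives the power double
# Lomax (PDLomax), F_P(x) = G(x)^lambda; reflecting gives the reverse power
# double Lomax (RPDLomax), F_RP(x) = 1 - G(-x)^lambda.  Both are skewed for
# lambda != 1 and collapse to the DLomax at lambda = 1, which makes their
# cdfs useful as asymmetric link functions for imbalanced binary regression.

.p_eps <- 1e-12

.check_sigma <- function(sigma) {
  if (any(!is.finite(sigma)) || any(sigma <= 0))
    stop("`sigma` must be a positive finite number", call. = FALSE)
}

.check_lambda <- function(lam) {
  if (length(lam) != 1L || !is.finite(lam) || lam <= 0)
    stop("`lambda` must be a single positive finite number", call. = FALSE)
}

# log of the standard (mu = 0, sigma = 1) DLomax cdf, stable in both tails
.log_G <- function(x) {
  out <- numeric(length(x))
  lo <- !is.na(x) & x <= 0
  hi <- !is.na(x) & x > 0
  # x <= 0: G = 1 / (2 (1 - x))
  out[lo] <- -log(2) - log1p(-x[lo])
  # x > 0: G = 1 - 1/(2(1+x)) = (1 + 2x) / (2 (1 + x))
  out[hi] <- log1p(2 * x[hi]) - log(2) - log1p(x[hi])
  out[is.na(x)] <- NA_real_
  out
}

#' Double Lomax distribution
#'
#' Density, distribution function, quantile function and the building block
#' for the power transforms.  The DLomax distribution with location `mu` and
#' scale `sigma` has density
#' \deqn{g(x) = \frac{1}{2\sigma\,(1 + |x - \mu|/\sigma)^2}}
#' and a piecewise cdf equal to \eqn{1/[2(1 + (\mu - x)/\sigma)]} for
#' \eqn{x \le \mu} and \eqn{1 - 1/[2(1 + (x - \mu)/\sigma)]} otherwise.
#' `mu = 0`, `sigma = 1` is the standard case used by the link functions.
#'
#' @param x vector of quantiles.
#' @param p vector of probabilities in (0, 1).
#' @param mu location parameter.
#' @param sigma scale parameter, positive.
#' @return `dlomax_pdf` the density, `dlomax_cdf` the cdf (in \[0, 1\]),
#'   `dlomax_quantile` the quantile function.
#' @examples
#' dlomax_cdf(0)            # 0.5
#' dlomax_cdf(1)            # 0.75
#' dlomax_quantile(0.75)    # 1
#' @export
dlomax_cdf <- function(x, mu = 0, sigma = 1) {
  .check_sigma(sigma)
  z <- (x - mu) / sigma
  out <- numeric(length(z))
  lo <- !is.na(z) & z <= 0
  hi <- !is.na(z) & z > 0
  out[lo] <- 1 / (2 * (1 - z[lo]))
  out[hi] <- 1 - 1 / (2 * (1 + z[hi]))
  out[is.na(z)] <- NA_real_
  # limits at +-Inf come out right automatically (0 and 1)
  out[!is.na(z) & z == -Inf] <- 0
  out[!is.na(z) & z == Inf] <- 1
  out
}

#' @rdname dlomax_cdf
#' @export
dlomax_pdf <- function(x, mu = 0, sigma = 1) {
  .check_sigma(sigma)
  z <- (x - mu) / sigma
  out <- 1 / (2 * sigma * (1 + abs(z))^2)
  out[!is.finite(z)] <- 0
  out[is.na(z)] <- NA_real_
  out
}

#' @rdname dlomax_cdf
#' @export
dlomax_quantile <- function(p, mu = 0, sigma = 1) {
  .check_sigma(sigma)
  if (any(!is.na(p) & (p <= 0 | p >= 1)))
    stop("`p` must lie strictly between 0 and 1", call. = FALSE)
  out <- numeric(length(p))
  lo <- !is.na(p) & p <= 0.5
  hi <- !is.na(p) & p > 0.5
  out[lo] <- mu - sigma * (1 / (2 * p[lo]) - 1)
  out[hi] <- mu + sigma * (1 / (2 * (1 - p[hi])) - 1)
  out[is.na(p)] <- NA_real_
  out
}

#' Power and reverse-power double Lomax distributions
#'
#' Standard (location 0, scale 1) PDLomax and RPDLomax distributions with
#' asymmetry parameter `lambda`: \eqn{F_P(x) = G(x)^\lambda} and
#' \eqn{F_{RP}(x) = 1 - G(-x)^\lambda}, with G the standard DLomax cdf.
#' `lambda = 1` recovers the symmetric DLomax; `lambda != 1` introduces
#' skew, which is what makes these cdfs useful links for imbalanced data.
#' The two families are reflections of each other:
#' `rpdlomax_cdf(x, lam) == 1 - pdlomax_cdf(-x, lam)`.
#'
#' Powers are computed as `exp(lambda * log G)` for numerical stability in
#' the tails.
#'
#' @param x vector of quantiles.
#' @param p vector of probabilities in (0, 1).
#' @param lam asymmetry parameter, a single positive number.
#' @return density, cdf or quantile values as numeric vectors.
#' @examples
#' pdlomax_cdf(0, lam = 2)       # 0.25
#' rpdlomax_cdf(0, lam = 2)      # 0.75
#' pdlomax_quantile(0.25, 2)     # 0
#' @export
pdlomax_cdf <- function(x, lam) {
  .check_lambda(lam)
  exp(lam * .log_G(x))
}

#' @rdname pdlomax_cdf
#' @export
pdlomax_pdf <- function(x, lam) {
  .check_lambda(lam)
  out <- lam * dlomax_pdf(x) * exp((lam - 1) * .log_G(x))
  out[!is.finite(x) & !is.na(x)] <- 0
  out
}

#' @rdname pdlomax_cdf
#' @export
rpdlomax_cdf <- function(x, lam) {
  .check_lambda(lam)
  -expm1(lam * .log_G(-x))
}

#' @rdname pdlomax_cdf
#' @export
rpdlomax_pdf <- function(x, lam) {
  pdlomax_pdf(-x, lam)
}

#' @rdname pdlomax_cdf
#' @export
pdlomax_quantile <- function(p, lam) {
  .check_lambda(lam)
  if (any(!is.na(p) & (p <= 0 | p >= 1)))
    stop("`p` must lie strictly between 0 and 1", call. = FALSE)
  dlomax_quantile(exp(log(p) / lam))
}

#' @rdname pdlomax_cdf
#' @export
rpdlomax_quantile <- function(p, lam) {
  .check_lambda(lam)
  if (any(!is.na(p) & (p <= 0 | p >= 1)))
    stop("`p` must lie strictly between 0 and 1", call. = FALSE)
  -dlomax_quantile(exp(log1p(-p) / lam))
}

.link_names <- c("logit", "probit", "cauchit", "loglog", "cloglog",
                 "dlomax", "pdlomax", "rpdlomax")

#' Link specification for binary regression
#'
#' Constructs a link object pairing a named cdf with, for the power links
#' (`pdlomax`, `rpdlomax`), an asymmetry parameter `lambda`.  The classical
#' links use their standard conventions: loglog is `exp(-exp(-eta))` and
#' cloglog is `1 - exp(-exp(eta))`.
#'
#' @param name one of `"logit"`, `"probit"`, `"cauchit"`, `"loglog"`,
#'   `"cloglog"`, `"dlomax"`, `"pdlomax"`, `"rpdlomax"`.
#' @param lambda asymmetry parameter for `pdlomax`/`rpdlomax` (default 1,
#'   which collapses both to the DLomax); ignored, with a warning, for the
#'   other links.
#' @return an object of class `lomax_link` with fields `name`, `lambda`
#'   (NULL for lambda-free links) and `has_lambda`.
#' @examples
#' lomax_link("rpdlomax", lambda = 2)
#' lomax_link("logit")
#' @export
lomax_link <- function(name, lambda = NULL) {
  name <- match.arg(name, .link_names)
  has_lambda <- name %in% c("pdlomax", "rpdlomax")
  if (has_lambda) {
    if (is.null(lambda)) lambda <- 1
    .check_lambda(lambda)
  } else if (!is.null(lambda)) {
    warning(sprintf("`lambda` is ignored for the %s link", name))
    lambda <- NULL
  }
  structure(list(name = name, lambda = lambda, has_lambda = has_lambda),
            class = "lomax_link")
}

#' @export
print.lomax_link <- function(x, ...) {
  if (x$has_lambda)
    cat(sprintf("<%s link, lambda = %g>\n", x$name, x$lambda))
  else
    cat(sprintf("<%s link>\n", x$name))
  invisible(x)
}

#' Success probability under a link
#'
#' Maps a linear predictor to a success probability, `p = F(eta)`, where F
#' is the cdf named by the link.  Probabilities are clipped to
#' `[1e-12, 1 - 1e-12]` by default so downstream log-likelihoods stay
#' finite for extreme linear predictors.
#'
#' @param eta numeric vector of linear predictor values.
#' @param link a [lomax_link()] object.
#' @param clip clip probabilities away from 0 and 1 (default TRUE).
#' @return probabilities, same length as `eta`.
#' @examples
#' link_prob(0, lomax_link("logit"))                       # 0.5
#' link_prob(0, lomax_link("rpdlomax", lambda = 0.256))    # 1 - 0.5^0.256
#' @export
link_prob <- function(eta, link, clip = TRUE) {
  stopifnot(inherits(link, "lomax_link"))
  p <- switch(link$name,
    logit    = stats::plogis(eta),
    probit   = stats::pnorm(eta),
    cauchit  = stats::pcauchy(eta),
    loglog   = exp(-exp(-eta)),
    cloglog  = -expm1(-exp(eta)),
    dlomax   = dlomax_cdf(eta),
    pdlomax  = pdlomax_cdf(eta, link$lambda),
    rpdlomax = rpdlomax_cdf(eta, link$lambda)
  )
  if (clip) p <- pmin(pmax(p, .p_eps), 1 - .p_eps)
  p
}

#' Power Cauchy success probability
#'
#' The power Cauchy response function
#' \eqn{p = (\arctan(\eta)/\pi + 1/2)^\lambda}, used as the data-generating
#' link in the misspecification study.
#'
#' @param eta numeric vector of linear predictor values.
#' @param lam asymmetry parameter, positive.
#' @return probabilities in (0, 1).
#' @examples
#' power_cauchy_prob(0, 1)   # 0.5
#' power_cauchy_prob(0, 2)   # 0.25
#' @export
power_cauchy_prob <- function(eta, lam) {
  .check_lambda(lam)
  exp(lam * stats::pcauchy(eta, log.p = TRUE))
}

#' Random variates from a link distribution
#'
#' Inverse-transform sampling from the distribution whose cdf the link
#' names.  Used for fixture generation and distributional checks.
#'
#' @param link a [lomax_link()] object.
#' @param n number of draws.
#' @param seed optional integer seed; when given the stream is reproducible.
#' @return numeric vector of length `n`.
#' @export
random_variates <- function(link, n, seed = NULL) {
  stopifnot(inherits(link, "lomax_link"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  u <- stats::runif(n)
  switch(link$name,
    logit    = stats::qlogis(u),
    probit   = stats::qnorm(u),
    cauchit  = stats::qcauchy(u),
    loglog   = -log(-log(u)),
    cloglog  = log(-log1p(-u)),
    dlomax   = dlomax_quantile(u),
    pdlomax  = pdlomax_quantile(u, link$lambda),
    rpdlomax = rpdlomax_quantile(u, link$lambda)
  )
}
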