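# Model comparison metrics and residual diagnostics.
#
# Deviance-based criteria (DIC, EAIC, EBIC) use the posterior mean of the
# deviance and the deviance at the posterior-mean parameters; WAIC and LOO
# are fully Bayesian and built from the pointwise predictive density over
# draws.  LOO is estimated with truncated importance sampling
# (w = min(r, sqrt(S) * mean(r)), r = 1/p(y_i | theta)) and reported on the
# deviance scale, LOO = -2 * elpd, so its magnitude is directly comparable
# to WAIC.

.draws_from <- function(fit) {
  stopifnot(inherits(fit, "lomax_fit"))
  list(beta = fit$beta_draws, delta = fit$delta_draws,
       data = fit$data, link = fit$link)
}

# log(mean(exp(lx))) per column, max-shifted
.col_log_mean_exp <- function(lx) {
  m <- apply(lx, 2, max)
  m + log(colMeans(exp(sweep(lx, 2, m))))
}

#' Deviance summary and deviance-based criteria
#'
#' Computes the posterior mean deviance `D_bar`, the deviance at the
#' posterior-mean parameters `D_hat` (the mean of the `delta` draws, not of
#' `lambda`, is plugged in for the power links), the effective number of
#' parameters `rho_d = D_bar - D_hat`, and `DIC = D_bar + rho_d`,
#' `EAIC = D_bar + 2k`, `EBIC = D_bar + k log(n)`.
#'
#' @param fit a [fit_binreg()] result.
#' @return list of class `deviance_summary` with fields `D_bar`, `D_hat`,
#'   `rho_d`, `DIC`, `EAIC`, `EBIC`, `k`, `n`.
#' @export
deviance_summary <- function(fit) {
  dr <- .draws_from(fit)
  S <- nrow(dr$beta)
  if (S < 2L) stop("need at least 2 posterior draws", call. = FALSE)
  dev <- vapply(seq_len(S), function(s)
    -2 * log_likelihood(dr$beta[s, ], dr$delta[s], dr$data, dr$link), 0)
  D_bar <- mean(dev)
  D_hat <- -2 * log_likelihood(colMeans(dr$beta),
                               if (!is.null(dr$delta)) mean(dr$delta),
                               dr$data, dr$link)
  k <- ncol(dr$beta) + as.integer(dr$link$has_lambda)
  n <- dr$data$n
  rho_d <- D_bar - D_hat
  structure(list(D_bar = D_bar, D_hat = D_hat, rho_d = rho_d,
                 DIC = D_bar + rho_d, EAIC = D_bar + 2 * k,
                 EBIC = D_bar + k * log(n), k = k, n = n),
            class = "deviance_summary")
}

#' Watanabe-Akaike information criterion
#'
#' `WAIC = -2 (lppd_hat - p_waic)` with
#' `lppd_hat = sum_i log(mean_s p(y_i|theta_s))` and
#' `p_waic = 2 sum_i (log mean_s p - mean_s log p)`.
#'
#' @param fit a [fit_binreg()] result.
#' @return list of class `waic_result` with `lppd_hat`, `p_waic`, `WAIC`
#'   and the pointwise `lppd_i`.
#' @export
waic <- function(fit) {
  dr <- .draws_from(fit)
  if (nrow(dr$beta) < 2L) stop("need at least 2 posterior draws", call. = FALSE)
  ll <- .log_lik_matrix(dr$beta, dr$delta, dr$data, dr$link)
  lppd_i <- .col_log_mean_exp(ll)
  p_i <- 2 * (lppd_i - colMeans(ll))
  structure(list(lppd_hat = sum(lppd_i), p_waic = sum(p_i),
                 WAIC = -2 * (sum(lppd_i) - sum(p_i)), lppd_i = lppd_i),
            class = "waic_result")
}

#' Leave-one-out cross-validation by truncated importance sampling
#'
#' Estimates the expected log pointwise predictive density of
#' leave-one-out cross-validation without refitting: the raw importance
#' ratios `r_i^(s) = 1/p(y_i|theta_s)` are truncated at
#' `sqrt(S) * mean_s(r_i)` and
#' `elpd_i = log( sum_s w p / sum_s w )`.  `LOO = -2 * elpd` puts the
#' result on the deviance scale, comparable to WAIC.
#'
#' @param fit a [fit_binreg()] result.
#' @return list of class `loo_result` with `elpd_loo`, `LOO`, pointwise
#'   `elpd_i`, and `max_weight_frac` (largest single-draw share of the
#'   truncated weights per observation, a degeneracy diagnostic).
#' @export
psis_loo <- function(fit) {
  dr <- .draws_from(fit)
  S <- nrow(dr$beta)
  if (S < 2L) stop("need at least 2 posterior draws", call. = FALSE)
  ll <- .log_lik_matrix(dr$beta, dr$delta, dr$data, dr$link)   # S x n
  r <- exp(-ll)
  cap <- sqrt(S) * colMeans(r)
  w <- pmin(r, rep(cap, each = S))
  elpd_i <- log(colSums(w * exp(ll)) / colSums(w))
  structure(list(elpd_loo = sum(elpd_i), LOO = -2 * sum(elpd_i),
                 elpd_i = elpd_i,
                 max_weight_frac = apply(w, 2, max) / colSums(w)),
            class = "loo_result")
}

#' Randomized quantile residuals
#'
#' For a Bernoulli response with fitted success probability `p_hat_i` (the
#' posterior-mean predictive probability), draws
#' `u_i ~ U(0, 1 - p_hat_i)` when `y_i = 0` and `u_i ~ U(1 - p_hat_i, 1)`
#' when `y_i = 1`, and returns `qnorm(u_i)`.  Under a correctly specified
#' model the residuals are standard normal.
#'
#' @param fit a [fit_binreg()] result.
#' @param seed integer seed for the randomization (required for
#'   reproducibility).
#' @return numeric vector of length n.
#' @export
quantile_residuals <- function(fit, seed = 1L) {
  p_hat <- predict_prob(fit)$mean
  y <- fit$data$y
  set.seed(seed)
  u <- stats::runif(length(y),
                    min = ifelse(y == 1, 1 - p_hat, 0),
                    max = ifelse(y == 1, 1, 1 - p_hat))
  stats::qnorm(pmin(pmax(u, .p_eps), 1 - .p_eps))
}

#' Residual diagnostic plots
#'
#' Normal QQ-plot and residual-versus-index plot of the randomized
#' quantile residuals.
#'
#' @param fit a [fit_binreg()] result.
#' @param seed seed passed to [quantile_residuals()].
#' @return the residual vector, invisibly.
#' @export
plot_quantile_residuals <- function(fit, seed = 1L) {
  r <- quantile_residuals(fit, seed = seed)
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  stats::qqnorm(r, main = "Quantile residuals")
  stats::qqline(r)
  graphics::plot(r, xlab = "Index", ylab = "Quantile residual")
  graphics::abline(h = 0, lty = 2)
  invisible(r)
}

#' Model comparison table
#'
#' One row per fitted model with the deviance-based and fully Bayesian
#' criteria: `rho_d`, `D_bar`, `D_hat`, `DIC`, `EAIC`, `EBIC`, `LOO`,
#' `WAIC`.  Models whose sampler did not converge (Rhat above the
#' error-level threshold) are kept in the table but their metrics are
#' blanked (NA), mirroring how non-converged fits should be reported
#' rather than trusted.
#'
#' @param fits named list of [fit_binreg()] results.
#' @param blank_nonconverged blank metrics of non-converged fits
#'   (default TRUE).
#' @return data.frame of class `comparison_table`.
#' @export
comparison_table <- function(fits, blank_nonconverged = TRUE) {
  stopifnot(length(fits) >= 1)
  nm <- names(fits)
  if (is.null(nm)) nm <- vapply(fits, function(f) f$link$name, "")
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    if (blank_nonconverged && !f$converged)
      return(data.frame(model = nm[i], rho_d = NA_real_, D_bar = NA_real_,
                        D_hat = NA_real_, DIC = NA_real_, EAIC = NA_real_,
                        EBIC = NA_real_, LOO = NA_real_, WAIC = NA_real_,
                        converged = FALSE))
    ds <- deviance_summary(f)
    data.frame(model = nm[i], rho_d = ds$rho_d, D_bar = ds$D_bar,
               D_hat = ds$D_hat, DIC = ds$DIC, EAIC = ds$EAIC,
               EBIC = ds$EBIC, LOO = psis_loo(f)$LOO, WAIC = waic(f)$WAIC,
               converged = f$converged)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("comparison_table", "data.frame")
  out
}
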