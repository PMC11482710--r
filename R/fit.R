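# Posterior sampling front-end: fit configuration, fitting, summaries,
# predictions and draw export.

#' Sampler configuration
#'
#' @param chains number of chains (default 4; at least 2 for Rhat).
#' @param iterations iterations per chain, including warmup (default 5000).
#' @param warmup warmup iterations per chain (default 2500).
#' @param seed master seed; per-chain seeds are derived from it
#'   deterministically.
#' @return object of class `fit_config`.
#' @export
fit_config <- function(chains = 4, iterations = 5000, warmup = 2500,
                       seed = 1L) {
  stopifnot(chains >= 1, warmup >= 1, warmup < iterations)
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 warmup = as.integer(warmup),
                 seed = as.integer(seed)),
            class = "fit_config")
}

.summ_row <- function(x) {
  q <- stats::quantile(x, c(0.05, 0.5, 0.95), names = FALSE)
  c(mean = mean(x), sd = stats::sd(x), median = q[2], p5 = q[1], p95 = q[3])
}

#' Fit a Bayesian binary regression model
#'
#' Samples the posterior of the regression coefficients (and, for the
#' `pdlomax`/`rpdlomax` links, `delta = log(lambda)`) with a
#' Laplace-initialized adaptive Metropolis algorithm: the posterior mode
#' and Hessian are found numerically, the proposal covariance is the
#' inverse Hessian scaled by 2.38^2/d, and the global scale adapts during
#' warmup.  Chains are jittered around the mode and Rhat (split potential
#' scale reduction) is reported per parameter; a warning is raised when any
#' Rhat exceeds 1.05, and the fit is flagged as non-converged above 1.1.
#'
#' Summaries for `lambda` are computed by applying `exp` to the `delta`
#' draws (so the reported mean is `mean(exp(delta))`, not
#' `exp(mean(delta))`).
#'
#' @param data a [binary_dataset()].
#' @param link a [lomax_link()]; for power links the supplied `lambda`
#'   only initializes the chain, the parameter is estimated.
#' @param priors a [prior_spec()].
#' @param config a [fit_config()].
#' @return object of class `lomax_fit`: list with `beta_draws` (S x k),
#'   `delta_draws` (length S or NULL), `chain_id`, `report` (summary
#'   data.frame with Rhat), `accept_rate`, `converged`, plus the inputs.
#' @examples
#' d <- simulate_binary(lomax_link("logit"), beta = c(0, 1), n = 200,
#'                      seed = 1)
#' f <- fit_binreg(d, lomax_link("logit"),
#'                 config = fit_config(chains = 2, iterations = 400,
#'                                     warmup = 200, seed = 1))
#' f$report
#' @export
fit_binreg <- function(data, link, priors = prior_spec(),
                       config = fit_config()) {
  stopifnot(inherits(data, "binary_dataset"), inherits(link, "lomax_link"))
  if (data$n > 0 && data$n < data$k)
    stop("need at least as many observations as parameters", call. = FALSE)
  k <- data$k
  d <- k + as.integer(link$has_lambda)
  target <- .make_target(data, link, priors)

  # initialize beta at the logistic MLE when it exists, else zero
  beta0 <- rep(0, k)
  if (data$n >= k && data$n > 0) {
    g <- tryCatch(
      suppressWarnings(stats::glm.fit(data$X, data$y,
                                      family = stats::binomial())),
      error = function(e) NULL)
    if (!is.null(g) && all(is.finite(g$coefficients)))
      beta0 <- pmin(pmax(g$coefficients, -20), 20)
  }
  init <- beta0
  if (link$has_lambda) {
    delta0 <- min(max(log(link$lambda), priors$delta_low + 0.1),
                  priors$delta_high - 0.1)
    init <- c(init, .zeta_from_delta(delta0, priors))
  }

  prop <- .laplace_proposal(target, init, d)

  set.seed(config$seed)
  chain_seeds <- sample.int(.Machine$integer.max, config$chains)
  jitter_seeds <- sample.int(.Machine$integer.max, config$chains)

  keep <- config$iterations - config$warmup
  draws <- matrix(NA_real_, keep * config$chains, d)
  chain_id <- rep(seq_len(config$chains), each = keep)
  accept <- numeric(config$chains)
  for (ch in seq_len(config$chains)) {
    set.seed(jitter_seeds[ch])
    start <- prop$mode + 0.3 * drop(prop$L %*% stats::rnorm(d))
    res <- .run_chain(target, start, prop$L, config$iterations,
                      config$warmup, chain_seeds[ch])
    draws[chain_id == ch, ] <- res$draws
    accept[ch] <- res$accept
  }

  beta_draws <- draws[, seq_len(k), drop = FALSE]
  colnames(beta_draws) <- colnames(data$X)
  delta_draws <- NULL
  if (link$has_lambda)
    delta_draws <- .delta_from_zeta(draws[, d], priors)

  par_mat <- beta_draws
  if (link$has_lambda)
    par_mat <- cbind(par_mat, delta = delta_draws,
                     lambda = exp(delta_draws))
  report <- as.data.frame(t(apply(par_mat, 2, .summ_row)))
  report$rhat <- apply(par_mat, 2, .split_rhat, chain_id = chain_id)
  report <- cbind(parameter = rownames(report), report)
  rownames(report) <- NULL

  rhat_check <- report$rhat[report$parameter != "lambda"]
  rhat_check <- rhat_check[is.finite(rhat_check)]
  converged <- all(rhat_check <= 1.1)
  if (any(rhat_check > 1.05))
    warning(sprintf(
      "possible non-convergence: max Rhat = %.3f%s",
      max(rhat_check),
      if (!converged) " (exceeds the 1.1 error-level threshold)" else ""),
      call. = FALSE)

  structure(list(beta_draws = beta_draws, delta_draws = delta_draws,
                 chain_id = chain_id, report = report,
                 accept_rate = accept, converged = converged,
                 data = data, link = link, priors = priors,
                 config = config),
            class = "lomax_fit")
}

#' @export
print.lomax_fit <- function(x, ...) {
  cat(sprintf("Bayesian binary regression, %s link%s\n", x$link$name,
              if (x$link$has_lambda) " (lambda estimated)" else ""))
  cat(sprintf("n = %d, %d chains x %d kept draws, mean acceptance %.2f\n",
              x$data$n, x$config$chains,
              x$config$iterations - x$config$warmup, mean(x$accept_rate)))
  if (!x$converged) cat("WARNING: convergence not reached (Rhat > 1.1)\n")
  print(format(x$report, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Posterior mean point estimates
#'
#' @param fit a [fit_binreg()] result.
#' @return list with `beta` (posterior-mean coefficients) and `lambda`
#'   (posterior mean of exp(delta), or NULL for lambda-free links).
#' @export
point_estimates <- function(fit) {
  stopifnot(inherits(fit, "lomax_fit"))
  list(beta = colMeans(fit$beta_draws),
       lambda = if (fit$link$has_lambda) mean(exp(fit$delta_draws)) else NULL)
}

#' Posterior predictive success probabilities
#'
#' Evaluates `p = F_lambda(x'beta)` for every posterior draw at new design
#' points, together with the per-observation posterior mean probability.
#'
#' @param fit a [fit_binreg()] result (or a list with `beta_draws`,
#'   `delta_draws`, `link`).
#' @param Xnew design matrix with the same number of columns as the
#'   training design (intercept included); defaults to the training design.
#' @return list with `prob` (S x n_new matrix) and `mean` (length n_new).
#' @export
predict_prob <- function(fit, Xnew = NULL) {
  if (is.null(Xnew)) Xnew <- fit$data$X
  Xnew <- as.matrix(Xnew)
  if (ncol(Xnew) != ncol(fit$beta_draws))
    stop("`Xnew` has ", ncol(Xnew), " columns but the model has ",
         ncol(fit$beta_draws), " coefficients", call. = FALSE)
  S <- nrow(fit$beta_draws)
  eta <- Xnew %*% t(fit$beta_draws)            # n x S
  prob <- matrix(NA_real_, S, nrow(Xnew))
  for (s in seq_len(S))
    prob[s, ] <- link_prob(eta[, s], .link_at(fit$link, fit$delta_draws[s]))
  list(prob = prob, mean = colMeans(prob))
}

#' Export posterior draws as CSV
#'
#' One row per draw; columns are the coefficients, `delta`/`lambda` when
#' present, and the chain id.
#'
#' @param fit a [fit_binreg()] result.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_draws_csv <- function(fit, path) {
  df <- as.data.frame(fit$beta_draws)
  if (fit$link$has_lambda) {
    df$delta <- fit$delta_draws
    df$lambda <- exp(fit$delta_draws)
  }
  df$chain <- fit$chain_id
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export the fit report as JSON
#'
#' @param fit a [fit_binreg()] result.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_fit_report_json <- function(fit, path) {
  jsonlite::write_json(
    list(link = fit$link$name,
         lambda_estimated = fit$link$has_lambda,
         n = fit$data$n,
         converged = fit$converged,
         accept_rate = fit$accept_rate,
         summary = fit$report),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
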