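# Laplace-initialized adaptive random-walk Metropolis sampler.
#
# The posterior over (beta, delta) is low-dimensional and smooth, so a
# random-walk Metropolis chain whose proposal covariance is calibrated from
# the curvature at the posterior mode mixes well.  delta = log(lambda) has a
# bounded uniform prior; it is mapped to an unbounded coordinate zeta via a
# scaled logistic transform (Jacobian included in the target) so the chain
# never has to respect a hard boundary.  During warmup a Robbins-Monro
# recursion tunes the global proposal scale toward the 0.234 random-walk
# optimum.

.delta_from_zeta <- function(zeta, priors) {
  priors$delta_low +
    (priors$delta_high - priors$delta_low) * stats::plogis(zeta)
}

.zeta_from_delta <- function(delta, priors) {
  stats::qlogis((delta - priors$delta_low) /
                (priors$delta_high - priors$delta_low))
}

# log |d delta / d zeta|
.log_jacobian_zeta <- function(zeta, priors) {
  log(priors$delta_high - priors$delta_low) +
    stats::plogis(zeta, log.p = TRUE) + stats::plogis(-zeta, log.p = TRUE)
}

# unnormalized log target over the unconstrained vector
# theta = (beta, [zeta])
.make_target <- function(data, link, priors) {
  k <- data$k
  if (link$has_lambda) {
    function(theta) {
      beta <- theta[seq_len(k)]
      zeta <- theta[k + 1L]
      delta <- .delta_from_zeta(zeta, priors)
      log_likelihood(beta, delta, data, link) +
        sum(stats::dnorm(beta, 0, priors$beta_sd, log = TRUE)) +
        .log_jacobian_zeta(zeta, priors)
    }
  } else {
    function(theta) {
      log_likelihood(theta, NULL, data, link) +
        sum(stats::dnorm(theta, 0, priors$beta_sd, log = TRUE))
    }
  }
}

# posterior mode + proposal Cholesky factor from the inverse Hessian
.laplace_proposal <- function(target, init, d) {
  neg <- function(theta) {
    v <- target(theta)
    if (!is.finite(v)) 1e10 else -v
  }
  opt <- tryCatch(
    stats::optim(init, neg, method = "BFGS", hessian = TRUE,
                 control = list(maxit = 500, reltol = 1e-10)),
    error = function(e) NULL)
  mode <- if (is.null(opt)) init else opt$par
  Sigma <- NULL
  if (!is.null(opt)) {
    H <- opt$hessian
    Sigma <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(Sigma)) {
      Sigma <- (Sigma + t(Sigma)) / 2
      if (any(!is.finite(Sigma)) || any(diag(Sigma) <= 0)) Sigma <- NULL
    }
  }
  if (is.null(Sigma)) Sigma <- diag(d)
  scl <- 2.38^2 / d
  L <- tryCatch(t(chol(scl * Sigma)), error = function(e) NULL)
  if (is.null(L)) L <- diag(sqrt(scl * pmax(diag(Sigma), 1e-8)), d)
  list(mode = mode, L = L)
}

# one Metropolis chain; returns kept draws (rows) and acceptance rate
.run_chain <- function(target, start, L, iterations, warmup, seed) {
  set.seed(seed)
  d <- length(start)
  keep <- iterations - warmup
  draws <- matrix(NA_real_, keep, d)
  theta <- start
  lp <- target(theta)
  if (!is.finite(lp)) { theta <- numeric(d); lp <- target(theta) }
  log_s <- 0
  n_acc <- 0L
  for (i in seq_len(iterations)) {
    prop <- theta + exp(log_s) * drop(L %*% stats::rnorm(d))
    lp_prop <- target(prop)
    a <- exp(min(0, lp_prop - lp))
    if (is.finite(lp_prop) && stats::runif(1) < a) {
      theta <- prop; lp <- lp_prop
      if (i > warmup) n_acc <- n_acc + 1L
    }
    if (i <= warmup) {
      acc <- if (is.finite(lp_prop)) a else 0
      log_s <- log_s + (acc - 0.234) / i^0.6
      # keep the adapted scale within sane bounds
      log_s <- min(max(log_s, -5), 5)
    } else {
      draws[i - warmup, ] <- theta
    }
  }
  list(draws = draws, accept = n_acc / max(keep, 1L))
}

# split-Rhat (potential scale reduction) per column of a draws matrix
.split_rhat <- function(x, chain_id) {
  chains <- split(seq_along(chain_id), chain_id)
  halves <- list()
  for (idx in chains) {
    h <- length(idx) %/% 2L
    if (h < 2L) return(NA_real_)
    halves <- c(halves, list(x[idx[seq_len(h)]]),
                list(x[idx[(h + 1L):(2L * h)]]))
  }
  m <- length(halves)
  n <- length(halves[[1L]])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (!is.finite(W) || W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}
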