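# Shared fixtures: short sampler settings for unit tests, and a handmade
# fit-like object for tests that need draws without running MCMC.

quick_config <- function(seed = 1L, chains = 2, iterations = 600,
                         warmup = 300) {
  fit_config(chains = chains, iterations = iterations, warmup = warmup,
             seed = seed)
}

# minimal object that predict_prob()/comparison helpers accept
fake_fit <- function(beta_draws, delta_draws = NULL, link, data,
                     converged = TRUE) {
  structure(list(beta_draws = beta_draws, delta_draws = delta_draws,
                 chain_id = rep(1L, nrow(beta_draws)),
                 link = link, data = data, converged = converged),
            class = "lomax_fit")
}

write_toy_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}
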