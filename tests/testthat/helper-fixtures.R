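# Small fixtures built in code.

# micro model: single knot at 0, basis (1, t) -- the smallest grid the
# package supports; cheap enough for chain-level checks
micro_grid <- function() changepoint_grid(0)

micro_cohort <- function(n = 12, seed = 1, ...) {
  simulate_cohort(synth_config(n = n, grid = micro_grid(), seed = seed, ...))
}

micro_mdata <- function(n = 12, seed = 1, ...) {
  prepare_model_data(micro_cohort(n, seed, ...), micro_grid(),
                     covariates = NULL)
}

# quick single-chain fit on the micro model
micro_chain <- function(mdata, iterations = 1000, burnin = 500, thin = 5,
                        seed = 1, grid_size = 128, priors = NULL, ...) {
  if (is.null(priors))
    priors <- prior_spec(micro_grid(), Lambda = diag(2),
                         sigma_prior = "invwishart")
  run_chain(mdata, priors,
            mcmc_config(iterations = iterations, burnin = burnin,
                        thin = thin, seed = seed, grid_size = grid_size,
                        chains = 1, ...),
            seed = seed)
}
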