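# Shared fixtures: small item sets, plausible parameter draws, fast sampler
# settings for MCMC smoke tests.

toy_items <- function() {
  choice_items(
    x_ss = c(50, 30, 80, 20),
    t_ss = c(0, 5, 10, 0),
    x_ll = c(100, 60, 120, 55),
    t_ll = c(10, 30, 40, 7),
    time_unit = "days"
  )
}

# A support-respecting random parameter vector for any model, drawn from the
# package's population defaults.
random_params <- function(model_id, seed) {
  pop <- population_spec(model_id, n_participants = 1L, seed = seed)
  truth <- sample_population(pop)
  param_vector(model_id, unlist(truth[1, model_spec(model_id)$params]))
}

# Like random_params(), but re-draws until the decision scores on `items`
# are moderate, so reference computations via log(p) / log(1 - p) stay
# within double precision.
moderate_params <- function(model_id, items, seed, max_abs_score = 20) {
  for (s in seed + 0:49) {
    p <- random_params(model_id, s)
    z <- itcmodels:::decision_score(model_spec(model_id), p, items)$z
    if (max(abs(z)) < max_abs_score) return(p)
  }
  stop("no moderate parameter draw found for ", model_id)
}

fast_sampler <- function(n_chains = 2L, n_warmup = 300L, n_draws = 300L) {
  sampler_config(n_chains = n_chains, n_warmup = n_warmup, n_draws = n_draws,
                 min_ess = 50)
}

# Fabricated deterministic MAP fit whose posterior mode is exactly `mode_unc`
# (used to drive correlation machinery with known inputs).
fake_map_fit <- function(model_id, mode_unc, sd_unc = 1e-3) {
  spec <- model_spec(model_id)
  structure(
    list(model_id = spec$model_id, params = spec$params, method = "map",
         priors = default_priors(model_id), sampler = sampler_config(),
         seed = 1L, n_obs = 0L,
         map = list(mode = setNames(mode_unc, spec$params),
                    vcov = diag(sd_unc^2, length(spec$params)),
                    converged = TRUE, log_post = 0),
         draws = NULL, diagnostics = NULL, converged = TRUE),
    class = "itc_fit"
  )
}
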