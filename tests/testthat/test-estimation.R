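test_that("sampler defaults follow standard four-chain practice", {
  sc <- sampler_config()
  expect_equal(sc$n_chains, 4L)
  expect_equal(sc$n_warmup, 2000L)
  expect_equal(sc$n_draws, 2000L)
  expect_equal(sc$retained_draws, 8000L)
  expect_error(sampler_config(n_chains = 0), "n_chains")
})

test_that("MAP fitting recovers known generating values on a rich design", {
  fg <- factorial_grid()
  gen <- param_vector("exponential", k = 0.1, sigma = 0.05)
  ds <- simulate_choices("exponential", gen, fg, seed = 21)
  fit <- fit_individual("exponential", ds, method = "map", seed = 1)
  sm <- posterior_summary(fit)
  expect_true(fit$converged)
  k_row <- sm[sm$parameter == "k", ]
  s_row <- sm[sm$parameter == "sigma", ]
  expect_lt(abs(log(k_row$median) - log(0.1)), 0.3)
  expect_true(k_row$lo < k_row$median & k_row$median < k_row$hi)
  expect_lt(abs(log(s_row$median) - log(0.05)), 0.5)
})

test_that("MAP fits are deterministic and degenerate data return wide intervals", {
  km <- kirby_mcq()
  all_ll <- choice_dataset("p1", km, rep(1L, 27))
  f1 <- fit_individual("hyperbolic", all_ll, seed = 1)
  f2 <- fit_individual("hyperbolic", all_ll, seed = 1)
  expect_identical(posterior_summary(f1), posterior_summary(f2))
  sm <- posterior_summary(f1)
  k_row <- sm[sm$parameter == "k", ]
  # all-identical choices: k is weakly identified, so the interval is wide
  expect_gt(k_row$hi_unc - k_row$lo_unc, 1.5)
})

test_that("MCMC fitting matches MAP on the same data and is reproducible", {
  fg <- factorial_grid()
  gen <- param_vector("hyperbolic", k = 0.15, sigma = 0.04)
  ds <- simulate_choices("hyperbolic", gen, fg, seed = 31)
  sc <- fast_sampler()
  f1 <- fit_individual("hyperbolic", ds, method = "mcmc", sampler = sc,
                       seed = 5)
  f2 <- fit_individual("hyperbolic", ds, method = "mcmc", sampler = sc,
                       seed = 5)
  expect_identical(f1$draws, f2$draws)
  expect_equal(dim(f1$draws), c(2L, 300L, 2L))
  fmap <- fit_individual("hyperbolic", ds, method = "map", seed = 5)
  sm_mc <- posterior_summary(f1)
  sm_map <- posterior_summary(fmap)
  expect_equal(sm_mc$median_unc, sm_map$median_unc, tolerance = 0.1)
  expect_true(all(f1$diagnostics$rhat < 1.1))
})

test_that("hierarchical fitting returns correctly shaped draws for two participants", {
  tr <- sample_population(population_spec("exponential", 2, seed = 6))
  ds <- generate_dataset(tr, kirby_mcq(), seed = 7)
  sc <- fast_sampler(n_warmup = 150, n_draws = 150)
  hf <- fit_hierarchical("exponential", ds, sampler = sc, seed = 8)
  expect_s3_class(hf, "itc_hfit")
  expect_equal(dim(hf$pop_draws), c(2L, 150L, 4L)) # mu_k, mu_sigma, tau_k, tau_sigma
  expect_equal(dim(hf$ind_draws), c(2L, 150L, 2L, 2L))
  isum <- individual_summary(hf)
  expect_equal(nrow(isum), 4L)
  expect_true(all(isum$median > 0)) # constrained scale respects supports
  expect_error(fit_hierarchical("exponential", ds[ds$participant_id == "p001", ]),
               ">= 2 participants")
})

test_that("a common true parameter vector concentrates the population scale near zero", {
  shared <- population_spec("exponential", 12,
                            location = c(k = log(0.08), sigma = log(0.08)),
                            scale = c(k = 0, sigma = 0), seed = 9)
  ds <- generate_dataset(sample_population(shared), factorial_grid(), seed = 10)
  sc <- fast_sampler(n_warmup = 250, n_draws = 250)
  hf <- fit_hierarchical("exponential", ds, sampler = sc, seed = 11)
  tau_k <- as.vector(hf$pop_draws[, , "tau_k"])
  expect_gt(mean(tau_k < 0.4), 0.8)

  dispersed <- population_spec("exponential", 12,
                               location = c(k = log(0.08), sigma = log(0.08)),
                               scale = c(k = 1.5, sigma = 0), seed = 9)
  ds2 <- generate_dataset(sample_population(dispersed), factorial_grid(),
                          seed = 10)
  hf2 <- fit_hierarchical("exponential", ds2, sampler = sc, seed = 11)
  tau_k2 <- as.vector(hf2$pop_draws[, , "tau_k"])
  expect_gt(median(tau_k2), median(tau_k))
})

test_that("hierarchical and independent estimates agree on rich data", {
  tr <- sample_population(population_spec("hyperbolic", 8, seed = 13))
  fg <- factorial_grid()
  ds <- generate_dataset(tr, fg, seed = 14)
  sc <- fast_sampler(n_warmup = 250, n_draws = 250)
  hf <- fit_hierarchical("hyperbolic", ds, sampler = sc, seed = 15)
  isum <- individual_summary(hf, scale = "unconstrained")
  h_meds <- isum$median[isum$parameter == "k"]
  i_meds <- vapply(unique(ds$participant_id), function(pid) {
    f <- fit_individual("hyperbolic", ds[ds$participant_id == pid, ],
                        method = "map", seed = 1)
    sm <- posterior_summary(f)
    sm$median_unc[sm$parameter == "k"]
  }, numeric(1))
  expect_gt(cor(h_meds, i_meds, method = "spearman"), 0.9)
})

test_that("fit_individual refuses multi-participant data", {
  tr <- sample_population(population_spec("exponential", 2, seed = 1))
  ds <- generate_dataset(tr, kirby_mcq(), seed = 2)
  expect_error(fit_individual("exponential", ds), "single participant")
})
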