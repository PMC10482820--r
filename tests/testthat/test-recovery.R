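test_that("recovery plan enumeration is pure arithmetic", {
  plan <- recovery_plan(designs = "factorial_grid",
                        models = c("exponential", "hyperbolic"),
                        n_combos = 5, n_replicates = 3)
  counts <- plan_counts(plan)
  expect_equal(nrow(counts), 2L)
  expect_true(all(counts$response_sets == 15L))
  expect_equal(attr(counts, "total_response_sets"), 30L)
})

test_that("generating combos preserve joint structure and edge cases", {
  tr <- sample_population(population_spec("double_exponential", 40, seed = 3))
  combos <- sample_generating_combos(tr, 30, seed = 4)
  expect_equal(nrow(combos), 30L)
  # each combo is one participant's full vector: it must appear verbatim
  key_src <- apply(round(tr[, c("beta", "delta", "omega", "sigma")], 10), 1,
                   paste, collapse = "|")
  key_out <- apply(round(combos, 10), 1, paste, collapse = "|")
  expect_true(all(key_out %in% key_src))

  one <- sample_population(population_spec("hyperbolic", 1, seed = 5))
  c_one <- sample_generating_combos(one, 7, seed = 6)
  expect_equal(nrow(unique(c_one)), 1L)
  expect_equal(nrow(sample_generating_combos(tr, 0, seed = 1)), 0L)
  empty <- sample_population(population_spec("hyperbolic", 0, seed = 1))
  expect_error(sample_generating_combos(empty, 5), "empty")
})

test_that("resampled marginals match the source distribution", {
  tr <- sample_population(population_spec("hyperbolic", 200, seed = 7))
  combos <- sample_generating_combos(tr, 4000, seed = 8)
  ks <- suppressWarnings(stats::ks.test(log(combos$k), log(tr$k)))
  expect_gt(ks$p.value, 0.001)
})

test_that("a recovery cell has the full combo x replicate x parameter layout", {
  tr <- sample_population(population_spec("exponential", 6, seed = 9))
  combos <- sample_generating_combos(tr, 4, seed = 10)
  raw <- run_recovery_cell("exponential", kirby_mcq(), combos,
                           n_replicates = 3, method = "map", seed = 11)
  expect_equal(nrow(raw), 4L * 3L * 2L)
  expect_identical(
    raw,
    run_recovery_cell("exponential", kirby_mcq(), combos,
                      n_replicates = 3, method = "map", seed = 11))
})

test_that("recovery summary handles identity, toy, and shuffled inputs", {
  make_raw <- function(recovered) {
    n_c <- nrow(recovered)
    n_r <- dim(recovered)[3] %||% 1L
    NULL
  }
  gen <- c(-2, -1, 0, 1, 2)
  # identity: recovered == generating for every replicate
  rows <- expand.grid(combo = 1:5, replicate = 1:2)
  raw_id <- data.frame(
    combo = rows$combo, replicate = rows$replicate, parameter = "k",
    generating = exp(gen[rows$combo]), generating_unc = gen[rows$combo],
    median = exp(gen[rows$combo]), lo = exp(gen[rows$combo]),
    hi = exp(gen[rows$combo]), median_unc = gen[rows$combo],
    lo_unc = gen[rows$combo], hi_unc = gen[rows$combo], converged = TRUE
  )
  attr(raw_id, "model_id") <- "exponential"
  attr(raw_id, "n_combos") <- 5L
  attr(raw_id, "n_replicates") <- 2L
  class(raw_id) <- c("itc_recovery_raw", "data.frame")
  s_id <- summarize_recovery(raw_id)
  expect_equal(s_id$correlations$r, 1)
  expect_equal(s_id$correlations$ci_lo, 1)
  expect_equal(s_id$correlations$ci_hi, 1)
  expect_equal(s_id$flag_rate, 0)

  # averaged CI bounds are the plain means of per-replicate bounds (2x2 toy)
  raw_toy <- raw_id[raw_id$combo %in% 1:2, ]
  raw_toy$lo_unc <- c(-1, -2, -3, -4)
  raw_toy$hi_unc <- c(1, 2, 3, 4)
  attr(raw_toy, "model_id") <- "exponential"
  attr(raw_toy, "n_combos") <- 2L
  attr(raw_toy, "n_replicates") <- 2L
  class(raw_toy) <- c("itc_recovery_raw", "data.frame")
  s_toy <- summarize_recovery(raw_toy)
  est <- s_toy$estimates[order(s_toy$estimates$combo), ]
  expect_equal(est$lo_unc, c(mean(c(-1, -3)), mean(c(-2, -4))))
  expect_equal(est$hi_unc, c(mean(c(1, 3)), mean(c(2, 4))))

  # shuffled recoveries: per-replicate correlation interval covers 0
  set.seed(99)
  rows_s <- expand.grid(combo = 1:20, replicate = 1:40)
  g <- rnorm(20)
  shuffled <- unlist(lapply(1:40, function(r) sample(g)))
  raw_sh <- data.frame(
    combo = rows_s$combo, replicate = rows_s$replicate, parameter = "k",
    generating = exp(g[rows_s$combo]), generating_unc = g[rows_s$combo],
    median = exp(shuffled), lo = exp(shuffled), hi = exp(shuffled),
    median_unc = shuffled, lo_unc = shuffled, hi_unc = shuffled,
    converged = TRUE
  )
  attr(raw_sh, "model_id") <- "exponential"
  attr(raw_sh, "n_combos") <- 20L
  attr(raw_sh, "n_replicates") <- 40L
  class(raw_sh) <- c("itc_recovery_raw", "data.frame")
  s_sh <- summarize_recovery(raw_sh)
  expect_lt(s_sh$correlations$ci_lo, 0)
  expect_gt(s_sh$correlations$ci_hi, 0)
})

test_that("noiseless-limit recovery approaches the generating values", {
  set.seed(17)
  combos <- data.frame(k = 10^runif(8, -2, 0), sigma = 10^runif(8, -2, -0.5))
  raw <- run_recovery_cell("exponential", factorial_grid(), combos,
                           n_replicates = 1, method = "map", seed = 18)
  s <- summarize_recovery(raw)
  expect_true(all(s$correlations$r > 0.9))
  est_k <- s$estimates[s$estimates$parameter == "k", ]
  expect_lt(median(abs(est_k$median_unc - est_k$generating_unc)), 0.25)
})
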