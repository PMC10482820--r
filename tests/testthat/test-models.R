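test_that("discounted values match closed forms", {
  expect_equal(discounted_value("hyperbolic", c(k = 0.1, sigma = 1), 100, 10),
               50)
  # k -> 0 removes discounting entirely
  expect_equal(
    discounted_value("exponential", c(k = 1e-300, sigma = 1), 80, 186), 80)
  # generalized hyperbolic at s = 1 is plain hyperbolic
  expect_equal(
    discounted_value("generalized_hyperbolic",
                     c(k = 0.05, s = 1, sigma = 1), 60, 20), 30)
  expect_equal(
    discounted_value("constant_sensitivity",
                     c(alpha = 0.02, beta = 1, sigma = 1), 100, 10),
    100 * exp(-0.2))
})

test_that("multiplicative discounted values stay within [0, x]", {
  mult <- c("exponential", "hyperbolic", "double_exponential",
            "generalized_hyperbolic", "hyperboloid", "generalized_hyperbola",
            "constant_sensitivity")
  x <- c(5, 50, 500)
  t <- c(0, 10, 100)
  for (m in mult) {
    p <- random_params(m, seed = 11)
    v <- discounted_value(m, p, x, t)
    expect_true(all(v >= 0 & v <= x), info = m)
    expect_equal(discounted_value(m, p, x, 0), x, info = m)
  }
})

test_that("attribute-wise models have no per-option value", {
  for (m in c("proportional_difference", "itch", "tradeoff")) {
    expect_error(discounted_value(m, random_params(m, 1), 100, 10),
                 "no per-option value")
  }
})

test_that("parameter vectors are validated against supports", {
  expect_error(param_vector("hyperbolic", k = -1, sigma = 1), "support")
  expect_error(param_vector("hyperbolic", k = 0.1), "missing")
  expect_error(param_vector("hyperbolic", k = 0.1, sigma = 1, zzz = 2),
               "unknown")
  expect_error(param_vector("double_exponential",
                            beta = 0.01, delta = 0.1, omega = 0.5,
                            sigma = 1), "beta >= delta")
  expect_error(param_vector("tradeoff", gamma = 1, tau = 1, kappa = 1,
                            alpha = 1, theta = 0.5, epsilon = 1), "support")
  expect_error(param_vector("nosuchmodel", k = 1), "unknown model_id")
})

test_that("unconstrained transforms round-trip on every model", {
  for (m in list_models()) {
    p <- random_params(m, seed = 21)
    u <- params_to_unc(m, p)
    expect_true(all(is.finite(u)), info = m)
    back <- params_from_unc(m, u)
    expect_equal(as.numeric(back), as.numeric(p), tolerance = 1e-12, info = m)
  }
})

test_that("equal discounted utilities give a 50/50 choice", {
  # k chosen so V_LL = V_SS exactly: 100/(1 + 0.1*10) = 50
  it <- choice_items(50, 0, 100, 10, "days")
  for (sigma in c(0.01, 1, 50)) {
    expect_equal(
      choice_prob_ll("hyperbolic", c(k = 0.1, sigma = sigma), it), 0.5)
  }
})

test_that("proportional difference choice rule behaves as specified", {
  it <- choice_items(50, 0, 100, 10, "days")
  d <- attribute_differences(it)$d
  expect_equal(d, -0.5) # (100-50)/100 - 10/10
  for (sigma in c(0.5, 2, 20)) {
    expect_equal(choice_prob_ll("proportional_difference",
                                c(delta = -0.5, sigma = sigma), it), 0.5)
  }
  # immediacy degeneracy: with t_ss = 0 the delay term is 1 whatever t_ll is
  it2 <- choice_items(50, 0, 100, 200, "days")
  expect_equal(attribute_differences(it2)$d, -0.5)
  # delay-scaling invariance: d unchanged when both delays are scaled
  it3 <- choice_items(40, 12, 90, 36, "days")
  it4 <- choice_items(40, 12 * 7, 90, 36 * 7, "days")
  expect_equal(attribute_differences(it3)$d, attribute_differences(it4)$d)
})

test_that("ITCH with all weights zero is indifferent on any item", {
  p <- c(b1 = 0, b_xA = 0, b_xR = 0, b_tA = 0, b_tR = 0)
  expect_equal(choice_prob_ll("itch", p, toy_items()), rep(0.5, 4))
})

test_that("trade-off choice probability matches its limit form", {
  # gamma, tau -> 0: v_i -> x_i and w_i -> t_i
  it <- choice_items(50, 0, 100, 10, "days")
  p <- param_vector("tradeoff", gamma = 1e-9, tau = 1e-9, kappa = 1.5,
                    alpha = 2, theta = 1 + 1e-12, epsilon = 0.7)
  q_v <- 100 - 50
  q_w <- (1.5 / 2) * log1p(2 * 10)
  expected <- q_v^(1 / 0.7) / (q_v^(1 / 0.7) + q_w^(1 / 0.7))
  expect_equal(choice_prob_ll("tradeoff", p, it), expected, tolerance = 1e-6)
})

test_that("choice probabilities are probabilities", {
  for (m in list_models()) {
    for (seed in 1:3) {
      p <- random_params(m, seed)
      pr <- choice_prob_ll(m, p, toy_items())
      expect_true(all(pr > 0 & pr < 1), info = paste(m, seed))
    }
  }
})

test_that("model reduction identities hold to 1e-10", {
  withr_seed <- 1234
  set.seed(withr_seed)
  for (rep in 1:20) {
    x <- runif(2, 5, 500)
    t <- runif(2, 0, 120)
    k <- 10^runif(1, -3, 0)
    a <- 10^runif(1, -3, 0)
    b <- 10^runif(1, -3, 0)
    expect_equal(
      discounted_value("generalized_hyperbolic", c(k = k, s = 1, sigma = 1),
                       x, t),
      discounted_value("hyperbolic", c(k = k, sigma = 1), x, t),
      tolerance = 1e-10)
    expect_equal(
      discounted_value("hyperboloid", c(k = k, s = 1, sigma = 1), x, t),
      discounted_value("hyperbolic", c(k = k, sigma = 1), x, t),
      tolerance = 1e-10)
    expect_equal(
      discounted_value("generalized_hyperbola",
                       c(alpha = a, beta = a, sigma = 1), x, t),
      discounted_value("hyperbolic", c(k = a, sigma = 1), x, t),
      tolerance = 1e-10)
    expect_equal(
      discounted_value("constant_sensitivity",
                       c(alpha = a, beta = 1, sigma = 1), x, t),
      discounted_value("exponential", c(k = a, sigma = 1), x, t),
      tolerance = 1e-10)
    expect_lt(
      max(abs(discounted_value("double_exponential",
                               c(beta = b, delta = b / 2, omega = 1 - 1e-13,
                                 sigma = 1), x, t) -
              discounted_value("exponential", c(k = b, sigma = 1), x, t))),
      1e-10)
    expect_equal(
      discounted_value("double_exponential",
                       c(beta = b, delta = b, omega = 0.3, sigma = 1), x, t),
      discounted_value("exponential", c(k = b, sigma = 1), x, t),
      tolerance = 1e-10)
  }
})

test_that("scaling both amounts never flips a linear-value model's preference", {
  mult <- c("exponential", "hyperbolic", "double_exponential",
            "generalized_hyperbolic", "hyperboloid", "generalized_hyperbola",
            "constant_sensitivity")
  set.seed(99)
  items <- toy_items()
  for (m in mult) {
    p <- random_params(m, seed = 7)
    base <- discounted_value(m, p, items$x_ll, items$t_ll) -
      discounted_value(m, p, items$x_ss, items$t_ss)
    for (c_mult in c(0.1, 3, 50)) {
      scaled <- discounted_value(m, p, c_mult * items$x_ll, items$t_ll) -
        discounted_value(m, p, c_mult * items$x_ss, items$t_ss)
      expect_equal(sign(scaled), sign(base), info = paste(m, c_mult))
    }
  }
})

test_that("common-difference behaviour: exponential invariant, hyperbolic single-crossing", {
  p_exp <- c(k = 0.05, sigma = 1)
  p_hyp <- c(k = 0.05, sigma = 1)
  it <- choice_items(60, 2, 100, 30, "days")
  deltas <- seq(0, 300, by = 5)
  diff_exp <- vapply(deltas, function(dd) {
    discounted_value("exponential", p_exp, 100, 30 + dd) -
      discounted_value("exponential", p_exp, 60, 2 + dd)
  }, numeric(1))
  expect_true(all(sign(diff_exp) == sign(diff_exp[1])))
  diff_hyp <- vapply(deltas, function(dd) {
    discounted_value("hyperbolic", p_hyp, 100, 30 + dd) -
      discounted_value("hyperbolic", p_hyp, 60, 2 + dd)
  }, numeric(1))
  # single crossing, from smaller-sooner preferred to larger-later preferred
  expect_lte(sum(diff(sign(diff_hyp)) != 0), 1)
  expect_lt(diff_hyp[1], 0)
  expect_gt(diff_hyp[length(diff_hyp)], 0)
  crossing <- which(diff_hyp > 0)[1]
  expect_true(all(diff_hyp[seq_len(crossing - 1)] < 0))
  expect_true(all(diff_hyp[crossing:length(diff_hyp)] > 0))
})

test_that("dataset log-likelihood matches a brute-force Bernoulli computation", {
  it <- toy_items()[1:2, ]
  for (m in list_models()) {
    p <- moderate_params(m, it, seed = 31)
    pr <- choice_prob_ll(m, p, it)
    total <- 0
    for (c1 in 0:1) for (c2 in 0:1) {
      ds <- choice_dataset("p1", it, c(c1, c2))
      ll <- dataset_loglik(m, p, ds)
      manual <- sum(log(ifelse(c(c1, c2) == 1, pr, 1 - pr)))
      expect_equal(ll, manual, tolerance = 1e-10, info = m)
      total <- total + exp(ll)
    }
    expect_equal(total, 1, tolerance = 1e-10, info = m)
  }
})

test_that("log-likelihood edge cases", {
  it <- choice_items(c(50, 50), 0, c(100, 100), 10, "days")
  ds <- choice_dataset("p1", it, c(1, 0))
  # k at the indifference point: both items p = 0.5
  expect_equal(dataset_loglik("hyperbolic", c(k = 0.1, sigma = 2), ds),
               2 * log(0.5))
  empty <- ds[0, ]
  expect_equal(dataset_loglik("hyperbolic", c(k = 0.1, sigma = 2), empty), 0)
  ds_bad <- ds
  ds_bad$choice[1] <- 2L
  expect_error(dataset_loglik("hyperbolic", c(k = 0.1, sigma = 2), ds_bad),
               "0/1")
})

test_that("choice simulation is seeded, calibrated, and respects limits", {
  it <- toy_items()
  p <- c(k = 0.01, sigma = 0.2)
  d1 <- simulate_choices("hyperbolic", p, it, seed = 7)
  d2 <- simulate_choices("hyperbolic", p, it, seed = 7)
  expect_identical(d1, d2)
  expect_true(all(d1$choice %in% 0:1))

  # forced indifference on many items: LL rate within 3 binomial SEs of 0.5
  big <- choice_items(rep(50, 10000), 0, rep(100, 10000), 10, "days")
  ind <- simulate_choices("hyperbolic", c(k = 0.1, sigma = 1), big, seed = 42)
  se <- sqrt(0.25 / 10000)
  expect_lt(abs(mean(ind$choice) - 0.5), 3 * se)

  # enormous sigma with LL strictly dominant everywhere
  det <- simulate_choices("hyperbolic", c(k = 1e-6, sigma = 1e6),
                          toy_items(), seed = 1)
  expect_true(all(det$choice == 1L))
})
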