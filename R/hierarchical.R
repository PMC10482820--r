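# Hierarchical Bayesian estimation ------------------------------------------
#
# Participant-level parameters are modelled on the unconstrained scale as
# theta_i ~ Normal(mu, tau^2), independently per parameter, with conjugate
# hyperpriors mu ~ Normal(m0, s0^2) and tau^2 ~ Inv-Gamma(a0, b0). Sampling
# alternates adaptive Metropolis block updates of each participant's theta_i
# (given their own likelihood and the population prior) with exact Gibbs
# draws of mu and tau^2.

# Vectorized unconstrained -> constrained transform over a draws matrix
# (columns = parameters). Avoids per-row validation overhead.
unc_matrix_to_constrained <- function(model_id, u) {
  spec <- model_spec(model_id)
  out <- u
  for (nm in spec$params) {
    out[, nm] <- switch(spec$support[[nm]],
      positive = exp(u[, nm]),
      "unit-interval" = plogis(u[, nm]),
      geq1 = 1 + exp(u[, nm]),
      unconstrained = u[, nm]
    )
  }
  if (spec$model_id == "double_exponential") {
    out[, "beta"] <- out[, "delta"] + exp(u[, "beta"])
  }
  out
}

#' Default hierarchical hyperpriors
#'
#' `mu ~ Normal(m0, s0^2)` centred at the synthetic-population default
#' locations with `s0 = 2.5`, and `tau^2 ~ Inv-Gamma(a0 = 2, b0 = 0.5)`
#' (prior mean 0.5 for the population variance) per parameter.
#'
#' @param model_id Model identifier.
#' @return List with `m0`, `s0`, `a0`, `b0`.
#' @export
default_hyperpriors <- function(model_id) {
  spec <- model_spec(model_id)
  def <- .default_population[[spec$model_id]]
  list(m0 = def$location[spec$params], s0 = 2.5, a0 = 2, b0 = 0.5)
}

#' Fit a model hierarchically to a multi-participant dataset
#'
#' @param model_id Model identifier.
#' @param dataset An `itc_dataset` with at least 2 participants.
#' @param hyperpriors See [default_hyperpriors()].
#' @param sampler An [sampler_config()].
#' @param seed Integer seed.
#' @return An object of class `"itc_hfit"` holding population-level draws
#'   (`mu_*`, `tau_*`, unconstrained scale) and per-participant draws.
#' @export
fit_hierarchical <- function(model_id, dataset, hyperpriors = NULL,
                             sampler = sampler_config(), seed = 1L) {
  spec <- model_spec(model_id)
  pids <- unique(dataset$participant_id)
  n <- length(pids)
  if (n < 2L) stop_input("fit_hierarchical requires >= 2 participants")
  hp <- hyperpriors %||% default_hyperpriors(spec$model_id)
  d <- length(spec$params)

  per <- lapply(pids, function(pid) {
    rows <- dataset$participant_id == pid
    list(items = dataset_items(dataset[rows, , drop = FALSE]),
         choice = dataset$choice[rows])
  })
  loglik_i <- function(i, u) {
    names(u) <- spec$params
    tryCatch({
      p <- params_from_unc(spec$model_id, u)
      sum(pointwise_loglik(spec, p, per[[i]]$items, per[[i]]$choice))
    }, error = function(e) -Inf)
  }

  seeds <- split_seed(seed, sampler$n_chains)
  chains <- lapply(seq_len(sampler$n_chains), function(ci) {
    run_hier_chain(loglik_i, n, d, hp, sampler, seeds[ci])
  })

  pop_names <- c(paste0("mu_", spec$params), paste0("tau_", spec$params))
  pop_draws <- array(NA_real_,
                     c(sampler$n_chains, sampler$n_draws, 2L * d),
                     dimnames = list(NULL, NULL, pop_names))
  ind_draws <- array(NA_real_,
                     c(sampler$n_chains, sampler$n_draws, n, d),
                     dimnames = list(NULL, NULL, pids, spec$params))
  for (ci in seq_along(chains)) {
    pop_draws[ci, , ] <- chains[[ci]]$pop
    ind_draws[ci, , , ] <- chains[[ci]]$theta
  }

  diag_df <- diagnostics(pop_draws, max_rhat = sampler$max_rhat,
                         min_ess = sampler$min_ess)
  out <- list(
    model_id = spec$model_id, params = spec$params, participants = pids,
    sampler = sampler, seed = as.integer(seed), hyperpriors = hp,
    pop_draws = pop_draws, ind_draws = ind_draws,
    diagnostics = diag_df, converged = attr(diag_df, "pass")
  )
  class(out) <- "itc_hfit"
  out
}

run_hier_chain <- function(loglik_i, n, d, hp, sampler, seed) {
  with_seed(seed, {
    n_w <- sampler$n_warmup
    n_d <- sampler$n_draws
    mu <- hp$m0 + rnorm(d, 0, 0.2)
    tau2 <- rep(0.5, d)
    theta <- matrix(rep(mu, each = n), n, d) + matrix(rnorm(n * d, 0, 0.3), n, d)
    cur_ll <- vapply(seq_len(n), function(i) loglik_i(i, theta[i, ]),
                     numeric(1))
    log_step <- rep(log(0.25), n)
    pop_out <- matrix(NA_real_, n_d, 2L * d)
    theta_out <- array(NA_real_, c(n_d, n, d))
    for (it in seq_len(n_w + n_d)) {
      # participant-level Metropolis block updates
      for (i in seq_len(n)) {
        prop <- theta[i, ] + exp(log_step[i]) * rnorm(d)
        prop_ll <- loglik_i(i, prop)
        log_r <- (prop_ll + sum(stats::dnorm(prop, mu, sqrt(tau2), log = TRUE))) -
          (cur_ll[i] + sum(stats::dnorm(theta[i, ], mu, sqrt(tau2), log = TRUE)))
        acc <- is.finite(log_r) && log(runif(1)) < log_r
        if (acc) {
          theta[i, ] <- prop
          cur_ll[i] <- prop_ll
        }
        if (it <= n_w) {
          log_step[i] <- log_step[i] +
            (as.numeric(acc) - sampler$target_accept) / sqrt(it)
        }
      }
      # conjugate population updates, independently per parameter
      for (j in seq_len(d)) {
        prec <- n / tau2[j] + 1 / hp$s0^2
        mean_j <- (sum(theta[, j]) / tau2[j] + hp$m0[j] / hp$s0^2) / prec
        mu[j] <- rnorm(1, mean_j, sqrt(1 / prec))
        tau2[j] <- 1 / rgamma(1, hp$a0 + n / 2,
                              hp$b0 + 0.5 * sum((theta[, j] - mu[j])^2))
      }
      if (it > n_w) {
        pop_out[it - n_w, ] <- c(mu, sqrt(tau2))
        theta_out[it - n_w, , ] <- theta
      }
    }
    list(pop = pop_out, theta = theta_out)
  })
}

#' Per-participant summaries from a hierarchical fit
#'
#' @param hfit An `itc_hfit`.
#' @param scale `"constrained"` or `"unconstrained"`.
#' @return Data frame: `participant_id`, `parameter`, `median`, `lo`, `hi`.
#' @export
individual_summary <- function(hfit,
                               scale = c("constrained", "unconstrained")) {
  scale <- match.arg(scale)
  dm <- dim(hfit$ind_draws)
  rows <- list()
  for (i in seq_len(dm[3L])) {
    u <- matrix(aperm(hfit$ind_draws[, , i, , drop = FALSE],
                      c(2, 1, 3, 4)), dm[1] * dm[2], dm[4])
    colnames(u) <- hfit$params
    if (scale == "constrained") {
      u <- unc_matrix_to_constrained(hfit$model_id, u)
    }
    qs <- apply(u, 2, quantile, probs = c(0.5, 0.025, 0.975), names = FALSE)
    rows[[i]] <- data.frame(
      participant_id = hfit$participants[i], parameter = hfit$params,
      median = qs[1, ], lo = qs[2, ], hi = qs[3, ], row.names = NULL
    )
  }
  do.call(rbind, rows)
}

#' Population-level summaries from a hierarchical fit
#'
#' @param hfit An `itc_hfit`.
#' @return Data frame of medians and central 95% intervals for the
#'   population locations (`mu_*`) and scales (`tau_*`), unconstrained scale.
#' @export
population_summary <- function(hfit) {
  dm <- dim(hfit$pop_draws)
  u <- matrix(aperm(hfit$pop_draws, c(2, 1, 3)), dm[1] * dm[2], dm[3])
  colnames(u) <- dimnames(hfit$pop_draws)[[3L]]
  qs <- apply(u, 2, quantile, probs = c(0.5, 0.025, 0.975), names = FALSE)
  data.frame(parameter = colnames(u), median = qs[1, ], lo = qs[2, ],
             hi = qs[3, ], row.names = NULL)
}

#' @export
print.itc_hfit <- function(x, ...) {
  cat(sprintf(
    "<itc_hfit> %s, %d participants, %d chains x %d draws, converged: %s\n",
    x$model_id, length(x$participants), dim(x$pop_draws)[1L],
    dim(x$pop_draws)[2L], x$converged))
  print(population_summary(x))
  invisible(x)
}
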