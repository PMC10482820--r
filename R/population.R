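# Synthetic participant populations -----------------------------------------

# Default population distributions: independent normals on each parameter's
# unconstrained scale (log / logit / log(theta-1) / identity; the
# double-exponential `beta` entry is the location of log(beta - delta)).
# Locations are chosen to give plausible discounting and moderately noisy
# choice behaviour in design-native units; all are overridable in
# `population_spec()`.
.default_population <- list(
  exponential = list(
    location = c(k = log(0.1), sigma = log(0.1)),
    scale    = c(k = 1, sigma = 1)
  ),
  hyperbolic = list(
    location = c(k = log(0.1), sigma = log(0.1)),
    scale    = c(k = 1, sigma = 1)
  ),
  double_exponential = list(
    location = c(beta = log(0.1), delta = log(0.01), omega = 0,
                 sigma = log(0.1)),
    scale    = c(beta = 0.75, delta = 0.75, omega = 1, sigma = 1)
  ),
  generalized_hyperbolic = list(
    location = c(k = log(0.1), s = 0, sigma = log(0.1)),
    scale    = c(k = 1, s = 0.5, sigma = 1)
  ),
  hyperboloid = list(
    location = c(k = log(0.1), s = 0, sigma = log(0.1)),
    scale    = c(k = 1, s = 0.5, sigma = 1)
  ),
  generalized_hyperbola = list(
    location = c(alpha = log(0.1), beta = log(0.1), sigma = log(0.1)),
    scale    = c(alpha = 1, beta = 1, sigma = 1)
  ),
  constant_sensitivity = list(
    location = c(alpha = log(0.1), beta = 0, sigma = log(0.1)),
    scale    = c(alpha = 1, beta = 0.5, sigma = 1)
  ),
  additive_utility = list(
    location = c(alpha = 0, beta = 0, lambda = log(0.5), sigma = log(0.1)),
    scale    = c(alpha = 0.25, beta = 0.25, lambda = 1, sigma = 1)
  ),
  proportional_difference = list(
    location = c(delta = 0, sigma = log(2)),
    scale    = c(delta = 0.5, sigma = 1)
  ),
  itch = list(
    location = c(b1 = 0, b_xA = 0, b_xR = 0, b_tA = 0, b_tR = 0),
    scale    = c(b1 = 1, b_xA = 0.05, b_xR = 2, b_tA = 0.05, b_tR = 2)
  ),
  tradeoff = list(
    location = c(gamma = log(0.5), tau = log(0.5), kappa = log(1),
                 alpha = log(1), theta = log(0.5), epsilon = log(0.3)),
    scale    = c(gamma = 0.5, tau = 0.5, kappa = 0.5, alpha = 0.5,
                 theta = 0.5, epsilon = 0.5)
  )
)

#' Specify a synthetic participant population
#'
#' Participant-level parameters are drawn from independent normal
#' distributions on each parameter's unconstrained scale and mapped back to
#' the natural scale, so every sampled vector automatically respects its
#' support. Package defaults (documented per model in the source) are used
#' for any location/scale not supplied.
#'
#' @param model_id Model identifier.
#' @param n_participants Number of participants to sample.
#' @param location,scale Optional named numeric vectors overriding the
#'   default unconstrained-scale means / standard deviations (scales must be
#'   `>= 0`; a scale of 0 makes that parameter common to all participants).
#' @param seed Master seed; per-participant substream seeds are derived from
#'   it so any participant can be regenerated independently.
#' @return An object of class `"itc_population_spec"`.
#' @export
population_spec <- function(model_id, n_participants, location = NULL,
                            scale = NULL, seed = 1L) {
  spec <- model_spec(model_id)
  def <- .default_population[[spec$model_id]]
  loc <- def$location
  sc <- def$scale
  if (!is.null(location)) loc[names(location)] <- location
  if (!is.null(scale)) sc[names(scale)] <- scale
  bad <- setdiff(c(names(location), names(scale)), spec$params)
  if (length(bad)) {
    stop_input("unknown parameter(s) in population spec: ",
               paste(bad, collapse = ", "))
  }
  if (any(sc < 0)) stop_input("population scales must be >= 0")
  structure(
    list(model_id = spec$model_id, n_participants = as.integer(n_participants),
         location = loc[spec$params], scale = sc[spec$params],
         seed = as.integer(seed)),
    class = "itc_population_spec"
  )
}

#' Sample participant-level true parameters from a population
#'
#' @param pop An [population_spec()].
#' @return A data frame of class `"itc_truth"`: one row per participant with
#'   natural-scale parameter columns; the population spec and the
#'   per-participant seed ledger are stored as attributes, making any subset
#'   regenerable bit-identically.
#' @export
sample_population <- function(pop) {
  stopifnot(inherits(pop, "itc_population_spec"))
  spec <- model_spec(pop$model_id)
  n <- pop$n_participants
  seeds <- split_seed(pop$seed, n)
  if (n > 0L) {
    rows <- lapply(seq_len(n), function(i) {
      u <- with_seed(seeds[i],
                     rnorm(length(spec$params), pop$location, pop$scale))
      names(u) <- spec$params
      as.numeric(params_from_unc(spec$model_id, u))
    })
    out <- as.data.frame(do.call(rbind, rows))
    names(out) <- spec$params
    out <- cbind(participant_id = sprintf("p%03d", seq_len(n)), out,
                 stringsAsFactors = FALSE)
  } else {
    out <- as.data.frame(setNames(
      c(list(character(0)), rep(list(numeric(0)), length(spec$params))),
      c("participant_id", spec$params)
    ))
  }
  attr(out, "model_id") <- spec$model_id
  attr(out, "population_spec") <- pop
  attr(out, "seed_ledger") <- seeds
  class(out) <- c("itc_truth", "data.frame")
  out
}

truth_params <- function(truth, i) {
  spec <- model_spec(attr(truth, "model_id"))
  param_vector(spec$model_id, unlist(truth[i, spec$params]))
}

#' Generate a multi-participant choice dataset from sampled truth
#'
#' Simulates one Bernoulli response per participant x item under each
#' participant's true parameters. `items` may be a fixed item set shared by
#' all participants, or a function `function(params, seed)` returning a
#' per-participant item set (used for tailored designs, where each
#' participant's items depend on their own parameters).
#'
#' @param truth An [sample_population()] result.
#' @param items An [choice_items()] data frame, or a tailoring function.
#' @param seed Master seed; per-participant response (and tailoring) seeds
#'   are derived from it.
#' @return An `itc_dataset` with one row per participant x item; the
#'   generating truth table is attached as `attr(, "truth")`.
#' @export
generate_dataset <- function(truth, items, seed = 1L) {
  stopifnot(inherits(truth, "itc_truth"))
  model_id <- attr(truth, "model_id")
  n <- nrow(truth)
  if (n == 0L) stop_input("empty truth set")
  seeds <- split_seed(seed, 2L * n)
  dsets <- lapply(seq_len(n), function(i) {
    p <- truth_params(truth, i)
    it <- if (is.function(items)) items(p, seeds[n + i]) else items
    simulate_choices(model_id, p, it, seed = seeds[i],
                     participant_id = truth$participant_id[i])
  })
  out <- bind_datasets(dsets)
  attr(out, "truth") <- truth
  attr(out, "model_id") <- model_id
  out
}
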