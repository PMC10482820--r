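# Value functions, choice probabilities, log-likelihood, simulation ---------

#' Discounted value of a single option under a discounted-utility model
#'
#' Defined for the eight models that value options separately: the seven
#' multiplicative discounted-utility models, for which `0 <= V <= x`, and the
#' additive-utility model `V = x^alpha - lambda * t^beta`, which may be
#' negative. The three attribute-wise models (proportional difference, ITCH,
#' trade-off) have no per-option value and raise an error.
#'
#' @param model_id Model identifier.
#' @param params An [param_vector()] (or named numeric) for that model.
#' @param x Amount(s), `>= 0`.
#' @param t Delay(s) in the design-native time unit, `>= 0`.
#' @return Numeric vector of utilities.
#' @examples
#' discounted_value("hyperbolic", c(k = 0.1, sigma = 1), x = 100, t = 10)
#' @export
discounted_value <- function(model_id, params, x, t) {
  spec <- model_spec(model_id)
  if (spec$class != "du") {
    stop_input(spec$model_id, " is an attribute-wise model: ",
               "no per-option value function")
  }
  if (any(!is.finite(x)) || any(!is.finite(t)) || any(x < 0) || any(t < 0)) {
    stop_input("options require finite x >= 0 and t >= 0")
  }
  p <- as.list(params)
  v <- switch(spec$model_id,
    exponential = x * exp(-p$k * t),
    hyperbolic = x / (1 + p$k * t),
    double_exponential =
      x * (p$omega * exp(-p$beta * t) + (1 - p$omega) * exp(-p$delta * t)),
    generalized_hyperbolic = x / (1 + p$k * t^p$s),
    hyperboloid = x / (1 + p$k * t)^p$s,
    generalized_hyperbola = x / (1 + p$alpha * t)^(p$beta / p$alpha),
    constant_sensitivity = x * exp(-(p$alpha * t)^p$beta),
    additive_utility = x^p$alpha - p$lambda * t^p$beta
  )
  if (any(!is.finite(v))) {
    stop_input(spec$model_id, ": non-finite discounted value")
  }
  v
}

# Decision score z and link per item. The probability of choosing the
# larger-later option is link(z):
#   discounted utility (7 multiplicative + additive): z = sigma*(V_LL - V_SS),
#     logistic link
#   proportional difference: z = sigma*(d - delta), probit link (higher sigma
#     = more deterministic, per the reparameterized likelihood)
#   ITCH: z = b1 + b_xA*dx + b_xR*dx/x* + b_tA*dt + b_tR*dt/t*, logistic link
#   trade-off: z = (log Q_v - log Q_w)/epsilon, logistic link, which equals
#     Q_v^(1/eps) / (Q_v^(1/eps) + Q_w^(1/eps)) in a form stable for small
#     epsilon
decision_score <- function(spec, params, items) {
  spec <- model_spec(spec)
  p <- as.list(params)
  if (spec$class == "du") {
    v_ll <- discounted_value(spec, params, items$x_ll, items$t_ll)
    v_ss <- discounted_value(spec, params, items$x_ss, items$t_ss)
    z <- p$sigma * (v_ll - v_ss)
    link <- "logistic"
  } else if (spec$model_id == "proportional_difference") {
    d <- attribute_differences(items)$d
    z <- p$sigma * (d - p$delta)
    link <- "probit"
  } else if (spec$model_id == "itch") {
    ad <- attribute_differences(items)
    z <- p$b1 + p$b_xA * ad$dx + p$b_xR * ad$dx / ad$x_star +
      p$b_tA * ad$dt + p$b_tR * ad$dt / ad$t_star
    link <- "logistic"
  } else { # tradeoff
    v_ll <- log1p(p$gamma * items$x_ll) / p$gamma
    v_ss <- log1p(p$gamma * items$x_ss) / p$gamma
    w_ll <- log1p(p$tau * items$t_ll) / p$tau
    w_ss <- log1p(p$tau * items$t_ss) / p$tau
    q_v <- v_ll - v_ss
    q_w <- (p$kappa / p$alpha) *
      log1p(p$alpha * ((w_ll - w_ss) / p$theta)^p$theta)
    if (any(q_v <= 0)) stop_input("tradeoff: Q_v not positive (invalid item?)")
    if (any(q_w <= 0)) stop_input("tradeoff: Q_w not positive (invalid item?)")
    z <- (log(q_v) - log(q_w)) / p$epsilon
    link <- "logistic"
  }
  if (any(!is.finite(z))) {
    stop_input(spec$model_id, ": non-finite decision score")
  }
  list(z = z, link = link)
}

#' Probability of choosing the larger-later option
#'
#' For the discounted-utility models this is the logistic choice rule
#' `p = L(sigma * (V_LL - V_SS))`; the proportional-difference model uses a
#' probit rule on its difference statistic; ITCH a logistic rule on its
#' weighted attribute differences; the trade-off model the ratio rule
#' `Q_v^(1/eps) / (Q_v^(1/eps) + Q_w^(1/eps))`, evaluated in log space.
#'
#' @inheritParams discounted_value
#' @param items An [choice_items()] data frame.
#' @return Numeric vector of probabilities.
#' @export
choice_prob_ll <- function(model_id, params, items) {
  sc <- decision_score(model_id, params, items)
  if (sc$link == "probit") pnorm(sc$z) else plogis(sc$z)
}

# Per-row log Bernoulli likelihood, computed in log space so probabilities of
# exactly 0/1 cannot arise from rounding.
pointwise_loglik <- function(spec, params, items, choice) {
  sc <- decision_score(spec, params, items)
  if (sc$link == "probit") {
    lp1 <- pnorm(sc$z, log.p = TRUE)
    lp0 <- pnorm(-sc$z, log.p = TRUE)
  } else {
    lp1 <- plogis(sc$z, log.p = TRUE)
    lp0 <- plogis(-sc$z, log.p = TRUE)
  }
  ifelse(choice == 1L, lp1, lp0)
}

#' Log-likelihood of a choice dataset under a model
#'
#' Sums, over rows, `log p_LL` where the larger-later option was chosen
#' (`choice = 1`) and `log(1 - p_LL)` where the smaller-sooner was chosen
#' (`choice = 0`).
#'
#' @inheritParams choice_prob_ll
#' @param dataset A data frame with the item columns plus a `choice` column
#'   coded 1 = larger-later chosen, 0 = smaller-sooner chosen (e.g. an
#'   `itc_dataset`).
#' @return A scalar log-likelihood (`<= 0`; 0 for an empty dataset).
#' @export
dataset_loglik <- function(model_id, params, dataset) {
  if (nrow(dataset) == 0L) return(0)
  ch <- dataset$choice
  if (is.null(ch) || !all(ch %in% c(0, 1))) {
    stop_input("dataset `choice` must be coded 0/1 (1 = larger-later chosen)")
  }
  sum(pointwise_loglik(model_spec(model_id), params, dataset, ch))
}

#' Simulate choices on a set of items
#'
#' Draws one Bernoulli response per item with success probability
#' [choice_prob_ll()]. Identical seeds produce identical datasets.
#'
#' @inheritParams choice_prob_ll
#' @param seed Integer seed (or `NULL` to use the current RNG stream).
#' @param participant_id Identifier stored with the simulated rows.
#' @return An `itc_dataset` data frame (see [choice_dataset()]).
#' @export
simulate_choices <- function(model_id, params, items, seed = NULL,
                             participant_id = "sim1") {
  p <- choice_prob_ll(model_id, params, items)
  choice <- with_seed(seed, rbinom(length(p), 1L, p))
  choice_dataset(
    participant_id = participant_id,
    items = items,
    choice = choice
  )
}
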