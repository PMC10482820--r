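# Model registry ------------------------------------------------------------
#
# Eleven inter-temporal choice models. Eight value the two options separately
# (seven multiplicative discounted-utility models plus the additive-utility
# model); three compare attributes directly across options (proportional
# difference, the inter-temporal choice heuristic / ITCH, and the trade-off
# model).
#
# Each entry records the parameter names, their supports, and the transform
# that maps each parameter to an unconstrained scale (the scale on which
# populations are specified, priors are placed, and samplers run):
#   positive        -> log
#   unit-interval   -> logit
#   >= 1            -> log(theta - 1)
#   unconstrained   -> identity
# The double-exponential model additionally uses an offset reparameterization
# (see `params_to_unc`) to enforce beta >= delta and break the
# (beta, omega) <-> (delta, 1 - omega) label-switching symmetry.

.model_registry <- list(
  exponential = list(
    label = "Exponential", class = "du",
    params = c("k", "sigma"),
    support = c(k = "positive", sigma = "positive")
  ),
  hyperbolic = list(
    label = "Hyperbolic", class = "du",
    params = c("k", "sigma"),
    support = c(k = "positive", sigma = "positive")
  ),
  double_exponential = list(
    label = "Double exponential", class = "du",
    params = c("beta", "delta", "omega", "sigma"),
    support = c(beta = "positive", delta = "positive",
                omega = "unit-interval", sigma = "positive")
  ),
  generalized_hyperbolic = list(
    label = "Generalized hyperbolic", class = "du",
    params = c("k", "s", "sigma"),
    support = c(k = "positive", s = "positive", sigma = "positive")
  ),
  hyperboloid = list(
    label = "Hyperboloid", class = "du",
    params = c("k", "s", "sigma"),
    support = c(k = "positive", s = "positive", sigma = "positive")
  ),
  generalized_hyperbola = list(
    label = "Generalized hyperbola", class = "du",
    params = c("alpha", "beta", "sigma"),
    support = c(alpha = "positive", beta = "positive", sigma = "positive")
  ),
  constant_sensitivity = list(
    label = "Constant sensitivity", class = "du",
    params = c("alpha", "beta", "sigma"),
    support = c(alpha = "positive", beta = "positive", sigma = "positive")
  ),
  additive_utility = list(
    label = "Additive utility", class = "du",
    params = c("alpha", "beta", "lambda", "sigma"),
    support = c(alpha = "positive", beta = "positive",
                lambda = "positive", sigma = "positive")
  ),
  proportional_difference = list(
    label = "Proportional difference", class = "attribute",
    params = c("delta", "sigma"),
    support = c(delta = "unconstrained", sigma = "positive")
  ),
  itch = list(
    label = "ITCH", class = "attribute",
    params = c("b1", "b_xA", "b_xR", "b_tA", "b_tR"),
    support = c(b1 = "unconstrained", b_xA = "unconstrained",
                b_xR = "unconstrained", b_tA = "unconstrained",
                b_tR = "unconstrained")
  ),
  tradeoff = list(
    label = "Trade-off", class = "attribute",
    params = c("gamma", "tau", "kappa", "alpha", "theta", "epsilon"),
    support = c(gamma = "positive", tau = "positive", kappa = "positive",
                alpha = "positive", theta = "geq1", epsilon = "positive")
  )
)

.support_transform <- c(positive = "log", "unit-interval" = "logit",
                        geq1 = "log(theta-1)", unconstrained = "identity")

#' List the available inter-temporal choice models
#'
#' @return Character vector of the 11 model identifiers.
#' @export
list_models <- function() names(.model_registry)

#' Model specification
#'
#' Returns the static description of one model: its parameter names, the
#' support of each parameter, the transform mapping it to the unconstrained
#' scale, and whether the model values options separately (`"du"`,
#' discounted-utility family) or compares attributes across options
#' (`"attribute"`).
#'
#' @param model_id One of [list_models()].
#' @return An object of class `"itc_model_spec"`.
#' @examples
#' model_spec("hyperbolic")
#' @export
model_spec <- function(model_id) {
  if (inherits(model_id, "itc_model_spec")) return(model_id)
  entry <- .model_registry[[as.character(model_id)]]
  if (is.null(entry)) {
    stop_input("unknown model_id: '", model_id, "'; see list_models()")
  }
  spec <- list(
    model_id = as.character(model_id),
    label = entry$label,
    class = entry$class,
    params = entry$params,
    support = entry$support,
    transform = unname(.support_transform[entry$support])
  )
  names(spec$transform) <- entry$params
  class(spec) <- "itc_model_spec"
  spec
}

#' @export
print.itc_model_spec <- function(x, ...) {
  cat(sprintf("<itc_model_spec> %s (%s)\n", x$label,
              if (x$class == "du") "discounted utility" else "attribute-wise"))
  print(data.frame(parameter = x$params, support = unname(x$support),
                   transform = unname(x$transform)))
  invisible(x)
}

#' Construct a validated parameter vector for a model
#'
#' @param model_id Model identifier (see [list_models()]).
#' @param ... Named parameter values, or a single named numeric vector/list.
#' @return Named numeric vector of class `"itc_params"` with a `model_id`
#'   attribute.
#' @examples
#' param_vector("hyperbolic", k = 0.1, sigma = 0.5)
#' @export
param_vector <- function(model_id, ...) {
  spec <- model_spec(model_id)
  dots <- list(...)
  if (length(dots) == 1L && is.null(names(dots)) &&
      (is.numeric(dots[[1L]]) || is.list(dots[[1L]]))) {
    dots <- as.list(dots[[1L]])
  }
  vals <- unlist(dots)
  missing <- setdiff(spec$params, names(vals))
  extra <- setdiff(names(vals), spec$params)
  if (length(missing)) {
    stop_input(spec$model_id, ": missing parameter(s) ",
               paste(missing, collapse = ", "))
  }
  if (length(extra)) {
    stop_input(spec$model_id, ": unknown parameter(s) ",
               paste(extra, collapse = ", "))
  }
  p <- as.numeric(vals[spec$params])
  names(p) <- spec$params
  check_support(spec, p)
  structure(p, model_id = spec$model_id, class = "itc_params")
}

check_support <- function(spec, p) {
  if (any(!is.finite(p))) {
    stop_input(spec$model_id, ": non-finite parameter value")
  }
  for (nm in spec$params) {
    v <- p[[nm]]
    ok <- switch(spec$support[[nm]],
      positive = v > 0,
      "unit-interval" = v > 0 && v < 1,
      geq1 = v >= 1,
      unconstrained = TRUE
    )
    if (!ok) {
      stop_input(spec$model_id, ": parameter '", nm,
                 "' = ", v, " outside its support (", spec$support[[nm]], ")")
    }
  }
  if (spec$model_id == "double_exponential" && p[["beta"]] < p[["delta"]]) {
    stop_input("double_exponential: requires beta >= delta ",
               "(impatient rate at least the patient rate)")
  }
  invisible(TRUE)
}

#' @export
print.itc_params <- function(x, ...) {
  cat(sprintf("<itc_params> %s\n", attr(x, "model_id")))
  print(setNames(as.numeric(x), names(x)))
  invisible(x)
}

# Transforms between the constrained (natural) and unconstrained scales ------

#' Map parameters to / from the unconstrained scale
#'
#' `params_to_unc` maps a constrained parameter vector to the unconstrained
#' scale used for population distributions, priors, and sampling
#' (log / logit / log(theta - 1) / identity per parameter; the
#' double-exponential model maps `(beta, delta)` to
#' `(log(beta - delta), log(delta))` to enforce its ordering constraint).
#' `params_from_unc` is the inverse.
#'
#' @param model_id Model identifier.
#' @param p Named numeric vector on the constrained scale.
#' @param u Named numeric vector on the unconstrained scale (names are the
#'   parameter names).
#' @return A named numeric vector on the other scale.
#' @export
params_to_unc <- function(model_id, p) {
  spec <- model_spec(model_id)
  p <- p[spec$params]
  u <- numeric(length(p))
  names(u) <- spec$params
  for (nm in spec$params) {
    u[[nm]] <- switch(spec$support[[nm]],
      positive = log(p[[nm]]),
      "unit-interval" = logit(p[[nm]]),
      geq1 = log(p[[nm]] - 1),
      unconstrained = p[[nm]]
    )
  }
  if (spec$model_id == "double_exponential") {
    if (p[["beta"]] <= p[["delta"]]) {
      stop_input("double_exponential: beta must exceed delta strictly on ",
                 "the unconstrained scale")
    }
    u[["beta"]] <- log(p[["beta"]] - p[["delta"]])
  }
  u
}

#' @rdname params_to_unc
#' @export
params_from_unc <- function(model_id, u) {
  spec <- model_spec(model_id)
  u <- u[spec$params]
  p <- numeric(length(u))
  names(p) <- spec$params
  for (nm in spec$params) {
    p[[nm]] <- switch(spec$support[[nm]],
      positive = exp(u[[nm]]),
      "unit-interval" = inv_logit(u[[nm]]),
      geq1 = 1 + exp(u[[nm]]),
      unconstrained = u[[nm]]
    )
  }
  if (spec$model_id == "double_exponential") {
    p[["beta"]] <- p[["delta"]] + exp(u[["beta"]])
  }
  param_vector(spec$model_id, p)
}
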