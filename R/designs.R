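# The three choice-set designs ----------------------------------------------

#' The 27-item Kirby monetary choice questionnaire
#'
#' Returns the canonical 27-item instrument (Kirby, Petry & Bickel, 1999):
#' every item offers an immediate smaller reward ($11-$80) against a delayed
#' larger reward ($25-$85, 7-186 days), organised as 3 sets of 9 items of
#' increasing outcome magnitude (labelled `small`, `medium`, `large` in the
#' `subset` column). The packaged item table is validated against those
#' structural facts at load time.
#'
#' @return An [choice_items()] data frame with 27 rows, delays in days.
#' @export
kirby_mcq <- function() {
  path <- system.file("extdata", "kirby_mcq_items.csv",
                      package = "itcmodels", mustWork = TRUE)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  items <- choice_items(
    x_ss = raw$x_ss, t_ss = 0,
    x_ll = raw$x_ll, t_ll = raw$t_ll,
    time_unit = "days", subset = raw$magnitude
  )
  stopifnot(
    nrow(items) == 27L,
    all(items$t_ss == 0),
    all(items$t_ll >= 7 & items$t_ll <= 186),
    all(items$x_ss >= 11 & items$x_ss <= 80),
    all(items$x_ll >= 25 & items$x_ll <= 85),
    all(table(items$subset) == 9L)
  )
  items
}

#' The 380-item amount-by-delay factorial grid
#'
#' Every item offers $100 now against $X in D months, with X taking the 20
#' values 120, 140, ..., 500 and D the 19 values 2, 4, ..., 38 months; every
#' combination appears exactly once (20 x 19 = 380 items).
#'
#' @return An [choice_items()] data frame with 380 rows, delays in months.
#' @export
factorial_grid <- function() {
  grid <- expand.grid(
    x_ll = seq(120, 500, by = 20),
    t_ll = seq(2, 38, by = 2)
  )
  choice_items(
    x_ss = 100, t_ss = 0,
    x_ll = grid$x_ll, t_ll = grid$t_ll,
    time_unit = "months", subset = NA_character_
  )
}

#' Participant-tailored effect choice sets
#'
#' Generates items in the style of an adjustment-tailored design: three
#' 100-item subsets, each structured to elicit one effect.
#'
#' * `delay_duration`: the larger-later delay is always twice the
#'   smaller-sooner delay, with short delays spanning 2-40 days.
#' * `common_difference`: the larger-later delay always exceeds the
#'   smaller-sooner delay by 30 days, short delays 2-40 days.
#' * `magnitude`: the larger-later amount is always twice the smaller-sooner
#'   amount, with small amounts spanning $2-$40.
#'
#' The free attribute (the larger-later amount for the delay subsets, the
#' delay pair's later member for the magnitude subset) is placed near the
#' supplied generating model's indifference point and perturbed by seeded
#' multiplicative jitter drawn uniformly in `[0.7, 1.3]`. This is a
#' self-contained surrogate for the original interactive adjustment
#' staircase, whose update rule is not reproduced here; it yields choice
#' rates that are neither degenerate nor exactly 50%.
#'
#' @param effect One of `"delay_duration"`, `"common_difference"`,
#'   `"magnitude"`.
#' @param model_id,params Generating model and parameter vector used to locate
#'   indifference points (delays in days).
#' @param n_per_effect Number of items in the subset (default 100).
#' @param seed Integer seed for the jitter and attribute sampling.
#' @return An [choice_items()] data frame, delays in days, `subset` set to the
#'   effect name.
#' @export
tailored_sets <- function(effect, model_id, params, n_per_effect = 100L,
                          seed = NULL) {
  effects <- c("delay_duration", "common_difference", "magnitude")
  if (!effect %in% effects) {
    stop_input("unknown effect '", effect, "'; expected one of ",
               paste(effects, collapse = ", "))
  }
  n <- as.integer(n_per_effect)
  with_seed(seed, {
    jitter <- runif(n, 0.7, 1.3)
    if (effect %in% c("delay_duration", "common_difference")) {
      t_ss <- round(seq(2, 40, length.out = n))
      t_ll <- if (effect == "delay_duration") 2 * t_ss else t_ss + 30
      x_ss <- sample(2:40, n, replace = TRUE)
      ind <- vapply(seq_len(n), function(i) {
        indifference_amount(model_id, params, x_ss[i], t_ss[i], t_ll[i])
      }, numeric(1))
      x_ll <- pmin(pmax(ind * jitter, 1.05 * x_ss), 4 * x_ss)
      x_ll <- round(x_ll, 2)
    } else {
      x_ss <- round(seq(2, 40, length.out = n))
      x_ll <- 2 * x_ss
      t_ss <- sample(2:40, n, replace = TRUE)
      ind <- vapply(seq_len(n), function(i) {
        indifference_delay(model_id, params, x_ss[i], x_ll[i], t_ss[i])
      }, numeric(1))
      t_ll <- round(pmin(pmax(ind * jitter, t_ss + 1), 200))
    }
    choice_items(x_ss = x_ss, t_ss = t_ss, x_ll = x_ll, t_ll = t_ll,
                 time_unit = "days", subset = effect)
  })
}

#' @rdname tailored_sets
#' @details `tailored_design()` binds the three effect subsets into the full
#'   300-item tailored set for one participant.
#' @export
tailored_design <- function(model_id, params, n_per_effect = 100L,
                            seed = NULL) {
  seeds <- split_seed(seed %||% sample.int(.Machine$integer.max, 1), 3L)
  parts <- Map(function(effect, s) {
    tailored_sets(effect, model_id, params, n_per_effect, seed = s)
  }, c("delay_duration", "common_difference", "magnitude"), seeds)
  out <- do.call(rbind, lapply(parts, as.data.frame))
  rownames(out) <- NULL
  attr(out, "time_unit") <- "days"
  class(out) <- c("itc_items", "data.frame")
  out
}

# Larger-later amount at which the generating model is indifferent on an item
# with fixed delays. Falls back to 2 * x_ss when no indifference point exists
# in (x_ss, 1000 * x_ss) (e.g. a model insensitive to the free attribute).
indifference_amount <- function(model_id, params, x_ss, t_ss, t_ll) {
  f <- function(x_ll) {
    it <- data.frame(x_ss = x_ss, t_ss = t_ss, x_ll = x_ll, t_ll = t_ll)
    decision_score(model_id, params, it)$z
  }
  lo <- x_ss * (1 + 1e-6)
  hi <- x_ss * 1000
  z_lo <- tryCatch(f(lo), error = function(e) NA_real_)
  z_hi <- tryCatch(f(hi), error = function(e) NA_real_)
  if (!is.finite(z_lo) || !is.finite(z_hi) || z_lo * z_hi > 0) {
    return(2 * x_ss)
  }
  uniroot(f, lower = lo, upper = hi, tol = 1e-6)$root
}

# Larger-later delay at which the generating model is indifferent on an item
# with fixed amounts. Falls back to 2 * t_ss + 30 when no root is bracketed.
indifference_delay <- function(model_id, params, x_ss, x_ll, t_ss) {
  f <- function(t_ll) {
    it <- data.frame(x_ss = x_ss, t_ss = t_ss, x_ll = x_ll, t_ll = t_ll)
    decision_score(model_id, params, it)$z
  }
  lo <- t_ss + 1e-3
  hi <- 2000
  z_lo <- tryCatch(f(lo), error = function(e) NA_real_)
  z_hi <- tryCatch(f(hi), error = function(e) NA_real_)
  if (!is.finite(z_lo) || !is.finite(z_hi) || z_lo * z_hi > 0) {
    return(2 * t_ss + 30)
  }
  uniroot(f, lower = lo, upper = hi, tol = 1e-4)$root
}
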