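#' Construct a set of inter-temporal choice items
#'
#' An item pits a smaller-sooner option (amount `x_ss` delivered after delay
#' `t_ss`) against a larger-later option (`x_ll` after `t_ll`). Amounts are in
#' currency units, delays in the design's native time unit (days or months);
#' no unit conversion is ever performed because rate-like model parameters are
#' unit-dependent.
#'
#' Items must satisfy `x_ll > x_ss`, `t_ll > t_ss`, `t_ll > 0`, and all values
#' must be finite and non-negative; degenerate items are rejected at
#' construction rather than handled downstream in likelihoods.
#'
#' @param x_ss,t_ss Amount and delay of the smaller-sooner option.
#' @param x_ll,t_ll Amount and delay of the larger-later option.
#' @param time_unit `"days"` or `"months"`.
#' @param subset Optional per-item subset label (e.g. magnitude tier or
#'   effect subset); `NA` when unused.
#' @return A `data.frame` of class `"itc_items"` with one row per item.
#' @examples
#' choice_items(x_ss = 50, t_ss = 0, x_ll = 100, t_ll = 30, time_unit = "days")
#' @export
choice_items <- function(x_ss, t_ss, x_ll, t_ll,
                         time_unit = c("days", "months"),
                         subset = NA_character_) {
  time_unit <- match.arg(time_unit)
  n <- max(length(x_ss), length(t_ss), length(x_ll), length(t_ll))
  items <- data.frame(
    x_ss = as.numeric(rep_len(x_ss, n)),
    t_ss = as.numeric(rep_len(t_ss, n)),
    x_ll = as.numeric(rep_len(x_ll, n)),
    t_ll = as.numeric(rep_len(t_ll, n)),
    subset = rep_len(as.character(subset), n),
    stringsAsFactors = FALSE
  )
  attr(items, "time_unit") <- time_unit
  class(items) <- c("itc_items", "data.frame")
  report <- validate_items(items)
  if (!all(report$pass)) {
    bad <- report[!report$pass, , drop = FALSE]
    stop_input(
      "invalid choice items at row(s) ",
      paste(unique(bad$row), collapse = ", "), ": ",
      paste(unique(bad$check), collapse = "; ")
    )
  }
  items
}

#' Validate choice items against the item invariants
#'
#' Reporting counterpart of the constructor checks: never raises, returns one
#' row per (item, failed-or-passed invariant).
#'
#' @param items A data frame with columns `x_ss`, `t_ss`, `x_ll`, `t_ll`.
#' @return A data frame with columns `row`, `check`, `pass`.
#' @export
validate_items <- function(items) {
  checks <- list(
    "amounts not strictly ordered" = items$x_ll > items$x_ss,
    "delays not strictly ordered"  = items$t_ll > items$t_ss,
    "larger-later delay not positive" = items$t_ll > 0,
    "negative amount" = items$x_ss >= 0 & items$x_ll >= 0,
    "negative delay"  = items$t_ss >= 0,
    "non-finite value" = is.finite(items$x_ss) & is.finite(items$t_ss) &
      is.finite(items$x_ll) & is.finite(items$t_ll)
  )
  out <- do.call(rbind, lapply(names(checks), function(nm) {
    ok <- checks[[nm]]
    ok[is.na(ok)] <- FALSE
    data.frame(row = seq_along(ok), check = nm, pass = ok,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Attribute differences used by attribute-wise models
#'
#' Computes, per item, the amount and delay differences `dx`, `dt`, the mean
#' reference points `x_star`, `t_star` used by the inter-temporal choice
#' heuristic, and the proportional-difference statistic
#' `d = (max(x) - min(x)) / max(x) - (max(t) - min(t)) / max(t)`,
#' where the max/min are taken over the two options' absolute attribute
#' values. For valid items `d` lies in `[-1, 1]`. Note the delay term equals
#' 1 whenever `t_ss = 0`, regardless of `t_ll`.
#'
#' @param items An `itc_items` data frame (or anything with the four columns).
#' @return A data frame with columns `dx`, `dt`, `x_star`, `t_star`, `d`.
#' @export
attribute_differences <- function(items) {
  ax_max <- pmax(abs(items$x_ll), abs(items$x_ss))
  ax_min <- pmin(abs(items$x_ll), abs(items$x_ss))
  at_max <- pmax(abs(items$t_ll), abs(items$t_ss))
  at_min <- pmin(abs(items$t_ll), abs(items$t_ss))
  data.frame(
    dx = items$x_ll - items$x_ss,
    dt = items$t_ll - items$t_ss,
    x_star = (items$x_ll + items$x_ss) / 2,
    t_star = (items$t_ll + items$t_ss) / 2,
    d = (ax_max - ax_min) / ax_max - (at_max - at_min) / at_max
  )
}

item_time_unit <- function(items) attr(items, "time_unit") %||% "days"

#' @export
print.itc_items <- function(x, ...) {
  cat(sprintf("<itc_items> %d items, delays in %s\n",
              nrow(x), item_time_unit(x)))
  print(as.data.frame(head(x, 6L)))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}
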