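# Parameter recovery pipeline -----------------------------------------------

#' Enumerate a parameter-recovery plan
#'
#' A plan crosses choice-set designs with models; each cell simulates
#' `n_combos` generating parameter combinations x `n_replicates` response
#' sets. At the defaults (100 x 100) each cell comprises 10000 simulated
#' response sets; the full 3-design x 11-model plan enumerates 330000.
#'
#' @param designs Character vector of design ids.
#' @param models Character vector of model ids.
#' @param n_combos,n_replicates Generating combinations per cell and
#'   simulated response sets per combination.
#' @return An object of class `"itc_recovery_plan"`.
#' @export
recovery_plan <- function(designs = c("kirby_mcq", "factorial_grid",
                                      "tailored"),
                          models = list_models(),
                          n_combos = 100L, n_replicates = 100L) {
  stopifnot(n_combos >= 1L, n_replicates >= 1L,
            length(designs) >= 1L, length(models) >= 1L)
  structure(
    list(designs = designs, models = models,
         n_combos = as.integer(n_combos),
         n_replicates = as.integer(n_replicates)),
    class = "itc_recovery_plan"
  )
}

#' @rdname recovery_plan
#' @param plan An `itc_recovery_plan`.
#' @return `plan_counts()`: data frame with one row per design x model cell
#'   and its `response_sets` count; the grand total is in
#'   `attr(, "total_response_sets")`.
#' @export
plan_counts <- function(plan) {
  stopifnot(inherits(plan, "itc_recovery_plan"))
  cells <- expand.grid(design = plan$designs, model = plan$models,
                       stringsAsFactors = FALSE)
  cells$response_sets <- plan$n_combos * plan$n_replicates
  attr(cells, "total_response_sets") <- sum(cells$response_sets)
  cells
}

#' @export
print.itc_recovery_plan <- function(x, ...) {
  counts <- plan_counts(x)
  cat(sprintf(
    "<itc_recovery_plan> %d design(s) x %d model(s), %d combos x %d replicates\n",
    length(x$designs), length(x$models), x$n_combos, x$n_replicates))
  cat(sprintf("  response sets per cell: %d, total: %d\n",
              x$n_combos * x$n_replicates,
              attr(counts, "total_response_sets")))
  invisible(x)
}

#' Sample generating parameter combinations
#'
#' Draws complete parameter vectors jointly, preserving any dependencies
#' between a model's parameters: each combination is one participant's full
#' vector, taken (for hierarchical fits) at one randomly sampled retained
#' draw, or (for a synthetic truth table) as that participant's true vector.
#'
#' @param source An `itc_truth` table or an `itc_hfit`.
#' @param n Number of combinations.
#' @param seed Integer seed.
#' @return Data frame (class `"itc_combos"`) with one row per combination,
#'   natural-scale parameter columns, and a `model_id` attribute.
#' @export
sample_generating_combos <- function(source, n, seed = 1L) {
  if (inherits(source, "itc_truth")) {
    model_id <- attr(source, "model_id")
    pn <- model_spec(model_id)$params
    if (nrow(source) == 0L) stop_input("empty generating source")
    idx <- with_seed(seed, sample.int(nrow(source), n, replace = TRUE))
    out <- as.data.frame(source)[idx, pn, drop = FALSE]
  } else if (inherits(source, "itc_hfit")) {
    model_id <- source$model_id
    pn <- source$params
    dm <- dim(source$ind_draws) # chain, draw, participant, param
    pick <- with_seed(seed, cbind(
      sample.int(dm[1L], n, replace = TRUE),
      sample.int(dm[2L], n, replace = TRUE),
      sample.int(dm[3L], n, replace = TRUE)
    ))
    u <- t(vapply(seq_len(n), function(i) {
      source$ind_draws[pick[i, 1L], pick[i, 2L], pick[i, 3L], ]
    }, numeric(length(pn))))
    colnames(u) <- pn
    out <- as.data.frame(unc_matrix_to_constrained(model_id, u))
  } else {
    stop_input("source must be an itc_truth or itc_hfit")
  }
  rownames(out) <- NULL
  attr(out, "model_id") <- model_id
  class(out) <- c("itc_combos", "data.frame")
  out
}

#' Run one parameter-recovery cell
#'
#' For every generating combination and replicate: simulate a response set on
#' the cell's items, refit the model independently, and record the posterior
#' median and central 95% interval per parameter. Non-converged fits are
#' flagged and retained, never dropped. Fully seeded: identical arguments
#' reproduce identical results.
#'
#' @param model_id Model identifier.
#' @param items An [choice_items()] set shared by all combos, or a function
#'   `function(params, seed)` that tailors items to each generating
#'   combination (the tailored-design rule: responses are generated on the
#'   item set belonging to the parameter donor).
#' @param combos An [sample_generating_combos()] data frame (or any data
#'   frame of natural-scale parameter columns).
#' @param n_replicates Response sets per combination.
#' @param method,sampler,priors Passed to [fit_individual()].
#' @param seed Master seed.
#' @return Long data frame of class `"itc_recovery_raw"`.
#' @export
run_recovery_cell <- function(model_id, items, combos, n_replicates = 1L,
                              method = "map", sampler = sampler_config(),
                              priors = NULL, seed = 1L) {
  spec <- model_spec(model_id)
  pn <- spec$params
  n_c <- nrow(combos)
  stopifnot(n_c >= 1L, n_replicates >= 1L)
  seeds <- matrix(split_seed(seed, n_c * (n_replicates + 1L)),
                  nrow = n_c)
  rows <- vector("list", n_c * n_replicates)
  k <- 0L
  for (ci in seq_len(n_c)) {
    gen <- param_vector(spec$model_id, unlist(combos[ci, pn]))
    gen_unc <- params_to_unc(spec$model_id, gen)
    it <- if (is.function(items)) items(gen, seeds[ci, n_replicates + 1L])
          else items
    for (ri in seq_len(n_replicates)) {
      s <- seeds[ci, ri]
      dset <- simulate_choices(spec$model_id, gen, it, seed = s)
      fit <- fit_individual(spec$model_id, dset, priors = priors,
                            method = method, sampler = sampler, seed = s)
      sm <- posterior_summary(fit)
      k <- k + 1L
      rows[[k]] <- data.frame(
        combo = ci, replicate = ri, parameter = sm$parameter,
        generating = as.numeric(gen[sm$parameter]),
        generating_unc = as.numeric(gen_unc[sm$parameter]),
        median = sm$median, lo = sm$lo, hi = sm$hi,
        median_unc = sm$median_unc, lo_unc = sm$lo_unc, hi_unc = sm$hi_unc,
        converged = fit$converged, row.names = NULL
      )
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "model_id") <- spec$model_id
  attr(out, "n_combos") <- n_c
  attr(out, "n_replicates") <- as.integer(n_replicates)
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("itc_recovery_raw", "data.frame")
  out
}

#' Summarize a recovery cell
#'
#' Per combination and parameter, averages the per-replicate posterior
#' medians and 95% interval bounds (the averaged interval is the headline
#' recovery measure). Per parameter, reports the correlation between
#' generating and recovered values: the point value correlates the
#' generating values with the replicate-averaged medians; the 95% interval
#' is the 2.5/97.5 percentile range of the per-replicate correlations
#' (requires at least 2 replicates, otherwise `NA`). Correlations are
#' computed on the unconstrained scale by default, where parameter values
#' spanning orders of magnitude are comparable.
#'
#' @param raw An [run_recovery_cell()] result with at least 2 combos.
#' @param scale `"unconstrained"` or `"constrained"` for the correlations.
#' @return List of class `"itc_recovery_summary"` with elements `estimates`
#'   (per combo x parameter averages), `correlations` (per parameter), and
#'   `flag_rate` (share of non-converged fits).
#' @export
summarize_recovery <- function(raw,
                               scale = c("unconstrained", "constrained")) {
  scale <- match.arg(scale)
  if (attr(raw, "n_combos") < 2L) {
    stop_input("recovery summary needs >= 2 generating combos")
  }
  med_col <- if (scale == "unconstrained") "median_unc" else "median"
  gen_col <- if (scale == "unconstrained") "generating_unc" else "generating"

  agg <- function(v, by) tapply(v, by, mean)
  by <- list(combo = raw$combo, parameter = raw$parameter)
  est <- aggregate(
    raw[, c("generating", "generating_unc", "median", "lo", "hi",
            "median_unc", "lo_unc", "hi_unc")],
    by = by, FUN = mean
  )
  est <- est[order(est$parameter, est$combo), ]
  rownames(est) <- NULL

  flag_rate <- mean(!raw$converged)
  if (flag_rate == 1) {
    warning("every fit in this cell was flagged non-converged",
            call. = FALSE)
  }

  pars <- unique(raw$parameter)
  n_rep <- attr(raw, "n_replicates")
  cors <- lapply(pars, function(pm) {
    esub <- est[est$parameter == pm, ]
    g <- esub[[gen_col]]
    r_point <- if (sd(g) == 0 || sd(esub[[med_col]]) == 0) NA_real_
               else cor(g, esub[[med_col]])
    ci <- c(NA_real_, NA_real_)
    if (n_rep >= 2L) {
      rsub <- raw[raw$parameter == pm, ]
      per_rep <- vapply(seq_len(n_rep), function(ri) {
        rr <- rsub[rsub$replicate == ri, ]
        rr <- rr[order(rr$combo), ]
        if (sd(rr[[gen_col]]) == 0 || sd(rr[[med_col]]) == 0) NA_real_
        else cor(rr[[gen_col]], rr[[med_col]])
      }, numeric(1))
      ci <- quantile(per_rep, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    }
    data.frame(parameter = pm, r = r_point, ci_lo = ci[1], ci_hi = ci[2])
  })
  out <- list(
    model_id = attr(raw, "model_id"),
    estimates = est,
    correlations = do.call(rbind, cors),
    flag_rate = flag_rate,
    n_combos = attr(raw, "n_combos"),
    n_replicates = n_rep,
    scale = scale
  )
  class(out) <- "itc_recovery_summary"
  out
}

#' @export
print.itc_recovery_summary <- function(x, ...) {
  cat(sprintf(
    "<itc_recovery_summary> %s: %d combos x %d replicates (%.1f%% flagged)\n",
    x$model_id, x$n_combos, x$n_replicates, 100 * x$flag_rate))
  print(x$correlations)
  invisible(x)
}

#' Plot generating versus recovered parameter values
#'
#' Scatter of replicate-averaged recovered medians against generating values
#' with averaged 95% interval error bars and the identity line, one panel per
#' parameter. Requires ggplot2.
#'
#' @param summary An [summarize_recovery()] result.
#' @param scale `"unconstrained"` or `"constrained"` axes.
#' @return A ggplot object.
#' @export
plot_recovery <- function(summary,
                          scale = c("unconstrained", "constrained")) {
  scale <- match.arg(scale)
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop_input("plot_recovery requires the ggplot2 package")
  }
  est <- summary$estimates
  if (scale == "unconstrained") {
    df <- data.frame(parameter = est$parameter, gen = est$generating_unc,
                     rec = est$median_unc, lo = est$lo_unc, hi = est$hi_unc)
  } else {
    df <- data.frame(parameter = est$parameter, gen = est$generating,
                     rec = est$median, lo = est$lo, hi = est$hi)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = gen, y = rec)) +
    ggplot2::geom_abline(intercept = 0, slope = 1, linetype = "dotted",
                         colour = "blue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = lo, ymax = hi),
                           width = 0, alpha = 0.4) +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "generating value", y = "recovered value",
                  title = summary$model_id)
}
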