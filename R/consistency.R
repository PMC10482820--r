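# Cross-choice-set parameter consistency ------------------------------------

#' Fit a model separately to each labelled subset of a dataset
#'
#' Fits every participant independently within every subset of items (e.g.
#' the delay-duration / common-difference / magnitude effect subsets of a
#' tailored design). Participants missing rows in any subset are excluded
#' with a warning.
#'
#' @param model_id Model identifier.
#' @param dataset An `itc_dataset` with non-missing `subset` labels.
#' @param method,sampler,priors,seed Passed to [fit_individual()].
#' @return List of class `"itc_subset_fits"`: `fits[[subset]][[participant]]`.
#' @export
fit_by_subset <- function(model_id, dataset, method = "map",
                          sampler = sampler_config(), priors = NULL,
                          seed = 1L) {
  spec <- model_spec(model_id)
  if (all(is.na(dataset$subset))) {
    stop_input("dataset has no subset labels")
  }
  subsets <- sort(unique(dataset$subset[!is.na(dataset$subset)]))
  pids <- unique(dataset$participant_id)
  has_all <- vapply(pids, function(pid) {
    all(subsets %in% dataset$subset[dataset$participant_id == pid])
  }, logical(1))
  if (any(!has_all)) {
    warning("excluding participant(s) missing a subset: ",
            paste(pids[!has_all], collapse = ", "), call. = FALSE)
    pids <- pids[has_all]
  }
  if (length(pids) == 0L) stop_input("no participant has rows in every subset")
  seeds <- matrix(split_seed(seed, length(subsets) * length(pids)),
                  nrow = length(subsets))
  fits <- lapply(seq_along(subsets), function(si) {
    sub <- subsets[si]
    setNames(lapply(seq_along(pids), function(pi) {
      rows <- dataset$participant_id == pids[pi] & dataset$subset == sub
      fit_individual(spec$model_id, dataset[rows, , drop = FALSE],
                     priors = priors, method = method, sampler = sampler,
                     seed = seeds[si, pi])
    }), pids)
  })
  names(fits) <- subsets
  structure(
    list(model_id = spec$model_id, params = spec$params, method = method,
         subsets = subsets, participants = pids, fits = fits),
    class = "itc_subset_fits"
  )
}

#' Cross-subset correlations of individual parameter estimates
#'
#' For every parameter and every pair of subsets, estimates the correlation
#' across participants between the parameter values fitted from each subset
#' (on the unconstrained scale), with a 95% interval:
#'
#' * MCMC fits: draw-wise — at each retained draw index, participants'
#'   individual-level values from the two subsets are correlated; the
#'   interval is the 2.5/97.5 percentile range of those draw-wise
#'   correlations (a genuine credible interval).
#' * MAP fits: the point value correlates posterior modes; the interval is a
#'   nonparametric bootstrap over participants.
#'
#' A correlation is flagged `credible` when its interval excludes zero.
#' Constant estimates (zero variance across participants) yield a flagged
#' `degenerate` row rather than propagating `NaN`.
#'
#' @param sf An [fit_by_subset()] result with at least 2 subsets and 3
#'   participants.
#' @param n_boot Bootstrap replicates for MAP-mode intervals.
#' @param seed Seed for the bootstrap.
#' @return Data frame of class `"itc_consistency"`: `model`, `parameter`,
#'   `pair`, `r`, `ci_lo`, `ci_hi`, `credible`, `degenerate`.
#' @export
cross_subset_correlations <- function(sf, n_boot = 2000L, seed = 1L) {
  stopifnot(inherits(sf, "itc_subset_fits"))
  if (length(sf$subsets) < 2L) {
    stop_input(">= 2 subsets required for cross-subset correlations")
  }
  if (length(sf$participants) < 3L) {
    stop_input(">= 3 participants required for cross-subset correlations")
  }
  pairs <- utils::combn(sf$subsets, 2L, simplify = FALSE)
  pn <- sf$params
  use_draws <- sf$method == "mcmc"

  # participant x parameter matrices of unconstrained point estimates, and
  # (for mcmc) per-subset arrays [draw, participant, parameter]
  medians <- list()
  draws <- list()
  for (sub in sf$subsets) {
    fits <- sf$fits[[sub]]
    med <- t(vapply(fits, function(f) {
      sm <- posterior_summary(f)
      setNames(sm$median_unc, sm$parameter)[pn]
    }, numeric(length(pn))))
    medians[[sub]] <- med
    if (use_draws) {
      dr <- lapply(fits, posterior_draws, scale = "unconstrained")
      n_dr <- min(vapply(dr, nrow, integer(1)))
      keep <- round(seq(1L, n_dr, length.out = min(n_dr, 2000L)))
      draws[[sub]] <- array(
        unlist(lapply(dr, function(m) m[keep, pn, drop = FALSE])),
        dim = c(length(keep), length(pn), length(fits))
      )
    }
  }

  rows <- list()
  for (pr in pairs) {
    a <- pr[1L]; b <- pr[2L]
    for (j in seq_along(pn)) {
      xa <- medians[[a]][, j]
      xb <- medians[[b]][, j]
      degen <- sd(xa) == 0 || sd(xb) == 0
      if (degen) {
        rows[[length(rows) + 1L]] <- data.frame(
          model = sf$model_id, parameter = pn[j],
          pair = paste(a, b, sep = "/"), r = NA_real_, ci_lo = NA_real_,
          ci_hi = NA_real_, credible = NA, degenerate = TRUE
        )
        next
      }
      r_point <- cor(xa, xb)
      if (use_draws) {
        da <- draws[[a]][, j, ]
        db <- draws[[b]][, j, ]
        rs <- vapply(seq_len(nrow(da)), function(s) {
          va <- da[s, ]; vb <- db[s, ]
          if (sd(va) == 0 || sd(vb) == 0) NA_real_ else cor(va, vb)
        }, numeric(1))
        ci <- quantile(rs, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
        r_point <- median(rs, na.rm = TRUE)
      } else {
        n_p <- length(xa)
        rs <- with_seed(seed, vapply(seq_len(n_boot), function(bb) {
          idx <- sample.int(n_p, n_p, replace = TRUE)
          if (sd(xa[idx]) == 0 || sd(xb[idx]) == 0) NA_real_
          else cor(xa[idx], xb[idx])
        }, numeric(1)))
        ci <- quantile(rs, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        model = sf$model_id, parameter = pn[j],
        pair = paste(a, b, sep = "/"), r = r_point,
        ci_lo = ci[1], ci_hi = ci[2],
        credible = ci[1] > 0 || ci[2] < 0, degenerate = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("itc_consistency", "data.frame")
  out
}
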