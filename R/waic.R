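# WAIC and convergence diagnostics ------------------------------------------

#' Widely applicable information criterion (deviance scale)
#'
#' Given a pointwise log-likelihood matrix `ll` (S posterior draws by N
#' observations), computes
#' `lppd = sum_i log( mean_s exp(ll[s, i]) )`,
#' `p_waic = sum_i var_s(ll[s, i])`, and
#' `waic = -2 * (lppd - p_waic)`, with standard error
#' `se = sqrt(N * var_i(pointwise_i))` where
#' `pointwise_i = -2 * (lppd_i - p_waic_i)`.
#' Lower WAIC indicates better estimated out-of-sample predictive accuracy.
#'
#' @param ll Numeric matrix, draws in rows, observations in columns; all
#'   entries finite; at least 2 draws.
#' @return List of class `"itc_waic"` with elements `waic`, `se`, `p_waic`,
#'   `lppd`, and the per-observation `pointwise` data frame.
#' @export
waic <- function(ll) {
  ll <- as.matrix(ll)
  if (nrow(ll) < 2L) stop_input("waic needs at least 2 posterior draws")
  if (any(!is.finite(ll))) stop_input("non-finite pointwise log-likelihood")
  lppd_i <- apply(ll, 2, log_mean_exp)
  p_i <- apply(ll, 2, var)
  pointwise <- -2 * (lppd_i - p_i)
  out <- list(
    waic = sum(pointwise),
    se = sqrt(ncol(ll) * var(pointwise)),
    p_waic = sum(p_i),
    lppd = sum(lppd_i),
    pointwise = data.frame(lppd = lppd_i, p_waic = p_i, waic = pointwise)
  )
  class(out) <- "itc_waic"
  out
}

#' @export
print.itc_waic <- function(x, ...) {
  cat(sprintf("<itc_waic> waic = %.2f (se %.2f), p_waic = %.2f\n",
              x$waic, x$se, x$p_waic))
  invisible(x)
}

#' Convergence diagnostics: split-Rhat and effective sample size
#'
#' Computes, per parameter, the split-chain potential scale reduction factor
#' (each chain is split in half before comparing between- and within-chain
#' variances) and the effective sample size via the autocorrelation-sum
#' estimator with Geyer's initial-positive-sequence truncation.
#'
#' @param draws An `itc_fit` with MCMC draws, or a numeric array of dimension
#'   `[chain, draw, parameter]`. At least 2 chains are required.
#' @param max_rhat,min_ess Pass thresholds.
#' @return Data frame with columns `parameter`, `rhat`, `ess`, `pass`;
#'   attribute `"pass"` is the conjunction over parameters.
#' @export
diagnostics <- function(draws, max_rhat = 1.01, min_ess = 400) {
  if (inherits(draws, "itc_fit")) {
    if (is.null(draws$draws)) {
      stop_input("fit has no MCMC draws (MAP fits have no chain diagnostics)")
    }
    draws <- draws$draws
  }
  stopifnot(length(dim(draws)) == 3L)
  if (dim(draws)[1L] < 2L) stop_input("diagnostics require at least 2 chains")
  pn <- dimnames(draws)[[3L]] %||% paste0("par", seq_len(dim(draws)[3L]))
  out <- data.frame(
    parameter = pn,
    rhat = vapply(seq_along(pn), function(j) split_rhat(draws[, , j]),
                  numeric(1)),
    ess = vapply(seq_along(pn), function(j) ess_mean(draws[, , j]),
                 numeric(1))
  )
  out$pass <- out$rhat <= max_rhat & out$ess >= min_ess
  attr(out, "pass") <- all(out$pass)
  out
}

# mat: chains x draws
split_rhat <- function(mat) {
  n <- ncol(mat)
  half <- n %/% 2L
  pieces <- rbind(mat[, seq_len(half), drop = FALSE],
                  mat[, half + seq_len(half), drop = FALSE])
  m <- nrow(pieces)
  nn <- ncol(pieces)
  means <- rowMeans(pieces)
  vars <- apply(pieces, 1, var)
  W <- mean(vars)
  B <- nn * var(means)
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

ess_mean <- function(mat) {
  m <- nrow(mat)
  n <- ncol(mat)
  vars <- apply(mat, 1, var)
  W <- mean(vars)
  B <- if (m > 1) n * var(rowMeans(mat)) else 0
  var_plus <- (n - 1) / n * W + if (m > 1) B / n else 0
  if (var_plus == 0) return(m * n)
  max_lag <- min(n - 1L, 1000L)
  acov <- vapply(seq_len(m), function(j) {
    stats::acf(mat[j, ], lag.max = max_lag, plot = FALSE,
               type = "covariance", demean = TRUE)$acf[, 1, 1]
  }, numeric(max_lag + 1L))
  mean_acov <- rowMeans(acov)
  rho <- 1 - (W - mean_acov[-1L]) / var_plus
  # Geyer: sum consecutive pairs while their sum stays positive
  s <- 0
  t <- 1L
  while (t + 1L <= length(rho)) {
    pair <- rho[t] + rho[t + 1L]
    if (pair < 0) break
    s <- s + pair
    t <- t + 2L
  }
  ess <- m * n / (1 + 2 * s)
  min(ess, m * n)
}

#' Fit several models to a dataset and rank them by WAIC
#'
#' Each model is fit to every participant's rows independently (sharing draw
#' counts so pointwise log-likelihood matrices concatenate), and a single
#' WAIC over all rows is reported per model, ranked ascending (rank 1 =
#' best predictive accuracy).
#'
#' @param dataset An `itc_dataset`.
#' @param model_ids Models to compare (default: all 11).
#' @param method,sampler,seed Passed to [fit_individual()].
#' @return Data frame of class `"itc_waic_table"`: `model`, `waic`, `se`,
#'   `p_waic`, `rank`.
#' @export
compare_models <- function(dataset, model_ids = list_models(),
                           method = "map", sampler = sampler_config(),
                           seed = 1L) {
  pids <- unique(dataset$participant_id)
  seeds <- split_seed(seed, length(model_ids))
  rows <- lapply(seq_along(model_ids), function(mi) {
    mid <- model_ids[[mi]]
    lls <- lapply(pids, function(pid) {
      dsub <- dataset[dataset$participant_id == pid, , drop = FALSE]
      fit <- fit_individual(mid, dsub, method = method, sampler = sampler,
                            seed = seeds[mi], pointwise = TRUE)
      fit$pointwise_loglik
    })
    w <- waic(do.call(cbind, lls))
    data.frame(model = mid, waic = w$waic, se = w$se, p_waic = w$p_waic)
  })
  out <- do.call(rbind, rows)
  out$rank <- rank(out$waic, ties.method = "first")
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  class(out) <- c("itc_waic_table", "data.frame")
  out
}
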