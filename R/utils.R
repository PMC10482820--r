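#' @keywords internal
"_PACKAGE"

#' @importFrom stats plogis pnorm quantile runif rbinom rnorm rgamma optim
#'   optimHess median var cor sd setNames uniroot aggregate cov dnorm acf
#' @importFrom utils read.csv write.csv head combn
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards. seed = NULL leaves the global stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive `n` independent substream seeds from one master seed. Keeps every
# derived seed in [1, 2^31 - 2] so it is always a valid `set.seed()` argument.
split_seed <- function(seed, n) {
  if (n <= 0L) return(integer(0))
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

logit <- function(p) log(p) - log1p(-p)
inv_logit <- function(x) plogis(x)

# log(mean(exp(x))) without overflow, for WAIC's lppd term
log_mean_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(mean(exp(x - m)))
}

stop_input <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
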