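## Internal helpers: seeding, truncated draws, small assertions.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible substream seed from a master seed
#'
#' Every stochastic stage of the pipeline (schedule, ratings, choices,
#' neural, bootstrap, ...) draws its own seed from the master seed and a
#' stage name, so any stage can be re-run in isolation and still match a
#' full pipeline run.
#'
#' @param seed master seed (integer).
#' @param name character stage name.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @examples
#' substream_seed(1, "schedule")
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  m <- 2147483647 # 2^31 - 1, keeps everything in integer range
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% m
  as.integer((h + (abs(seed) %% m) * 48271) %% m)
}

## Evaluate `code` under `seed` without clobbering the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

## Truncated-normal draws by inverse-CDF; vectorised over n.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd <= 0) {
    return(rep(min(max(mean, lower), upper), n))
  }
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## Consistent impulsive/nonimpulsive coding used across the package.
CHOICE_LEVELS <- c("impulsive", "nonimpulsive")

is_choice <- function(x) all(x %in% CHOICE_LEVELS)
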