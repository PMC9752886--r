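# Shared internal helpers: classed conditions (mapped to CLI exit codes)
# and a seed scope that never leaks RNG state into the caller.

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("df_config_error", "df_error")))
}

stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("df_format_error", "df_error")))
}

stop_stage <- function(stage, ...) {
  stop(errorCondition(sprintf("[stage %s] %s", stage, paste0(...)),
                      class = c("df_stage_error", "df_error")))
}

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#'
#' All generators in the package are pure functions of (config, seed): they
#' run inside `with_seed()` so that identical inputs give byte-identical
#' outputs regardless of what the calling session did with the RNG before.
#'
#' @param seed integer scalar seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_config("seed must be a single non-missing number")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# log(sum(exp(x))) without overflow; used by the hypergeometric tail.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# canonical whitespace + case normalization for drug-name matching
norm_drug <- function(x) tolower(gsub("\\s+", " ", trimws(x)))

`%||%` <- function(a, b) if (is.null(a)) b else a
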