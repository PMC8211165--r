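#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, then restores the previous
#' RNG state, so seeded helpers do not perturb the caller's random stream.
#' With `seed = NULL` the code runs on the current stream unchanged.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

# scalar checks used by constructors
is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == floor(x)
is_prob <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x <= 1

ARM_LABELS <- c("left", "right")

# Map arm labels or 1/2 indices to integer index (1 = left, 2 = right).
arm_index <- function(arm) {
  if (is.character(arm)) {
    idx <- match(arm, ARM_LABELS)
    if (anyNA(idx)) stop_config("unknown arm label: %s",
                                paste(arm[is.na(idx)], collapse = ", "))
    return(idx)
  }
  arm <- as.integer(arm)
  if (any(is.na(arm) | arm < 1L | arm > 2L)) {
    stop_config("arm index must be 1 (left) or 2 (right)")
  }
  arm
}
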