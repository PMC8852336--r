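# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. Keeps generators deterministic without
# clobbering the user's random stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
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

# Derive a child seed from a root seed and a stream index, staying inside
# the 32-bit integer range R requires.
child_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + as.double(stream) * 129749) %% 2147483647
}

#' Trapezoidal area under a sampled curve
#'
#' Integrates `y` over `x` by the trapezoidal rule. Used to reduce a
#' time-by-ICC stability curve to a single area-under-the-curve summary
#' (units: ICC x seconds when `x` is duration in seconds).
#'
#' @param x numeric vector of strictly increasing abscissae.
#' @param y numeric vector of ordinates, same length as `x`.
#' @return a single number, the trapezoidal integral.
#' @examples
#' trapz(c(6, 60, 120), c(1, 1, 1))  # 114: constant curve of height 1
#' @export
trapz <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  if (length(x) < 2L) return(0)
  if (any(diff(x) <= 0)) stop("`x` must be strictly increasing", call. = FALSE)
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

stopifnot_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != as.integer(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
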