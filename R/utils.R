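#' Wrap phase angles to (-pi, pi]
#'
#' Maps arbitrary angles to the principal branch used throughout the
#' package.  The right-closed convention matches `Arg()`, so `-pi` maps
#' to `pi`.
#'
#' @param x numeric vector of angles, radians.
#' @return numeric vector of the same length, all values in `(-pi, pi]`.
#' @examples
#' wrap_phase(c(0, pi, -pi, 3 * pi))
#' @export
wrap_phase <- function(x) {
  pi - ((pi - x) %% (2 * pi))
}

# Scalar positive-number check used by constructors.
check_positive <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive finite number", what),
         call. = FALSE)
  }
  invisible(x)
}

check_nonnegative <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    stop(sprintf("`%s` must be a single non-negative finite number", what),
         call. = FALSE)
  }
  invisible(x)
}

# Evaluate `expr` with a private RNG stream seeded by `seed`, restoring
# the caller's RNG state afterwards so package functions never perturb
# user-level reproducibility.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
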