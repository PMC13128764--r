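#' @importFrom rlang .data abort warn inform %||%
#' @importFrom stats pt pf pchisq rnorm runif rbinom median sd setNames
#' @importFrom utils head
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL runs in the ambient stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Spawn a deterministic stream of sub-seeds from one parent seed, kept well
# inside 32-bit integer range.
spawn_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max %/% 4L, n))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x)
}

check_probability <- function(x, name) {
  if (!is_scalar_number(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single number in [0, 1].", name))
  }
  invisible(x)
}
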