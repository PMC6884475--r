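# Internal helpers: seeded evaluation and seed derivation.

# Evaluate `code` under a given RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
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
  }
  force(code)
}

#' Derive a stream seed from a master seed and a key path
#'
#' Pure integer mixing used to give every (group, agent, session, trial)
#' combination its own reproducible RNG stream. Character keys are folded
#' bytewise; the result is always in `[1, 2^31 - 1]`.
#'
#' @param master_seed Integer master seed.
#' @param ... Integer or character keys identifying the stream.
#' @return A single integer seed.
#' @examples
#' derive_seed(1, "ND", 3, "training", 12)
#' @export
derive_seed <- function(master_seed, ...) {
  keys <- list(...)
  h <- (as.numeric(master_seed) %% 2147483648) + 1
  mix <- function(h, k) ((h * 69069) %% 2147483648 + k + 1) %% 2147483648
  for (key in keys) {
    if (is.character(key)) {
      for (b in utf8ToInt(paste(key, collapse = "/"))) h <- mix(h, b)
    } else {
      for (k in as.numeric(key)) h <- mix(h, k %% 2147483648)
    }
    h <- mix(h, 101)
  }
  as.integer(h %% 2147483647 + 1)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Wrap an angle to (-pi, pi].
wrap_angle <- function(a) atan2(sin(a), cos(a))

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  }
  invisible(x)
}
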