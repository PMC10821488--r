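# Internal numeric helpers shared across modules.

DEG2RAD <- pi / 180
RAD2DEG <- 180 / pi
GRAVITY <- 9.80665  # m/s^2

#' @noRd
cumtrapz_ <- function(t, x) {
  n <- length(x)
  if (n < 2L) return(numeric(n))
  dt <- diff(t)
  c(0, cumsum(dt * (x[-n] + x[-1]) / 2))
}

#' @noRd
trapz_ <- function(t, x) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(t) * (x[-n] + x[-1]) / 2)
}

# Deterministic child seed derived from a root seed and a label; keeps all
# derived seeds in [0, 2^31). Randomness never touches the global RNG state
# outside local_seed_().
#' @noRd
child_seed_ <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((seed * 48271 + h) %% 2147483647)
}

# Evaluate expr with a local RNG seed, restoring the caller's RNG state.
#' @noRd
local_seed_ <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' @noRd
wm_log_ <- function(...) {
  message("[wheelmotion] ", sprintf(...))
}
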