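#' Run code with a temporary RNG seed
#'
#' Evaluates `expr` with the global RNG seeded to `seed` (Mersenne-Twister)
#' and restores the previous RNG state afterwards, so seeded simulation
#' helpers never perturb the caller's random stream.
#'
#' @param seed Integer seed (must be < 2^31).
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
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
  set.seed(as.integer(seed %% .Machine$integer.max), kind = "Mersenne-Twister")
  expr
}

# Deterministic sub-seed derivation: keeps every derived seed in [1, 2^31-2]
# so downstream set.seed() calls are portable 32-bit integers.
derive_seed <- function(seed, ...) {
  parts <- c(seed, unlist(list(...)))
  h <- 0
  for (p in parts) {
    v <- if (is.character(p)) sum(utf8ToInt(p) * seq_along(utf8ToInt(p))) else as.numeric(p)
    h <- (h * 69069 + v + 1) %% (.Machine$integer.max - 1)
  }
  as.integer(h + 1)
}

#' Trapezoidal integral of a sampled curve
#'
#' @param x Abscissa values (strictly increasing).
#' @param y Ordinate values, same length as `x`.
#' @return The trapezoidal approximation of the integral.
#' @keywords internal
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
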