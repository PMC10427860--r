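# Internal helpers: seeded RNG scoping, seed derivation, interpolation.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package operations never
#' disturb (or depend on) the caller's RNG state.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
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
  expr
}

# Deterministic stream splitting: derive a child seed from a base seed and an
# index.  Arithmetic stays below 2^53 so doubles are exact; the result stays
# below 2^31 so it is a valid R integer seed.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.numeric(seed) %% 2147483647
  for (k in idx) {
    s <- (s * 48271 + as.numeric(k) + 1) %% 2147483647
  }
  as.integer(s)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Bilinear upsampling of a small matrix onto an nr x nc grid; used to turn a
# coarse random field into a smooth low-frequency background.
bilinear_upsample <- function(m, nr, nc) {
  sr <- nrow(m)
  sc <- ncol(m)
  if (sr == 1L && sc == 1L) return(matrix(m[1, 1], nr, nc))
  # Map target pixel centers onto the coarse grid's [1, sr] x [1, sc] range.
  ri <- if (sr == 1L) rep(1, nr) else seq(1, sr, length.out = nr)
  ci <- if (sc == 1L) rep(1, nc) else seq(1, sc, length.out = nc)
  r0 <- clamp(floor(ri), 1, sr - 1)
  c0 <- clamp(floor(ci), 1, sc - 1)
  fr <- ri - r0
  fc <- ci - c0
  m00 <- m[cbind(rep(r0, nc), rep(c0, each = nr))]
  m10 <- m[cbind(rep(r0 + 1, nc), rep(c0, each = nr))]
  m01 <- m[cbind(rep(r0, nc), rep(c0 + 1, each = nr))]
  m11 <- m[cbind(rep(r0 + 1, nc), rep(c0 + 1, each = nr))]
  fr_full <- rep(fr, nc)
  fc_full <- rep(fc, each = nr)
  v <- m00 * (1 - fr_full) * (1 - fc_full) +
    m10 * fr_full * (1 - fc_full) +
    m01 * (1 - fr_full) * fc_full +
    m11 * fr_full * fc_full
  matrix(v, nr, nc)
}

stop_invalid <- function(...) stop(..., call. = FALSE)
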