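# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Draw `n` derived seeds (< 2^31) reproducibly from a base seed.
deriveSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Wrap phases into (-pi, pi]
#'
#' @param x numeric vector or matrix of phases (radians)
#' @return same shape, with every value mapped into (-pi, pi]
#' @export
#' @examples
#' wrapPhase(c(0, pi, -pi, 3 * pi / 2))
wrapPhase <- function(x) {
  out <- x
  # only touch values that actually need wrapping, so in-range phases
  # (and threshold comparisons against them) stay bit-exact
  idx <- which(x <= -pi | x > pi)
  if (length(idx)) {
    w <- ((x[idx] + pi) %% (2 * pi)) - pi
    w[w == -pi] <- pi
    out[idx] <- w
  }
  out
}
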