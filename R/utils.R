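## internal numerics and RNG helpers

# trapezoid rule on an arbitrary strictly increasing grid
.trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# deterministic sub-seed derivation; keeps results < 2^31 - 1 and positive
.deriveSeed <- function(master, index) {
  as.integer((as.numeric(master) %% 65536 * 32749 + index * 7919 + 1) %%
               2147483647)
}

# evaluate expr under a seed without disturbing the caller's RNG state
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# interpolate spectrum values onto a target grid, zero outside support
.onGrid <- function(s, grid) {
  if (identical(s@wavelength, grid)) return(s@value)
  stats::approx(s@wavelength, s@value, xout = grid, yleft = 0, yright = 0,
                rule = 1)$y -> v
  v[is.na(v)] <- 0
  v
}
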