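# internal helpers: seeded evaluation, seed splitting, FFT frequency grids

# evaluate `expr` under a temporary RNG state; the caller's stream is restored
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

#' Derive a stage sub-seed from a master seed
#'
#' Deterministic splitting so each pipeline stage gets an independent seed
#' that can be reproduced in isolation: the stage name is folded into the
#' master seed with a 31-multiplier polynomial hash modulo 2^31 - 1.
#'
#' @param seed integer master seed.
#' @param ... character/numeric tokens naming the stage
#'   (e.g. `"simulate"`, class label, replicate index).
#' @return a single integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' splitSeed(1, "simulate", "filament", 1)
splitSeed <- function(seed, ...) {
  tokens <- paste(vapply(list(...), as.character, ""), collapse = "/")
  h <- as.numeric(seed) %% 2147483647
  for (code in utf8ToInt(tokens)) h <- (h * 31 + code) %% 2147483647
  as.integer(h %% 2147483645 + 1)
}

# zero-centred discrete frequency indices in FFT (wrap-around) order
fftIndex <- function(n) {
  ((seq_len(n) - 1 + floor(n / 2)) %% n) - floor(n / 2)
}

# matrix of fx^2 + fy^2 (physical spatial frequency squared, cycles/m) in
# FFT order; rows follow v/Ny, columns u/Nx, matching dim (Ny, Nx)
freqSqGrid <- function(optics) {
  ny <- optics@dims[1]; nx <- optics@dims[2]
  dx <- optics@pixelPitch[1]; dy <- optics@pixelPitch[2]
  fu <- fftIndex(nx) / (nx * dx)
  fv <- fftIndex(ny) / (ny * dy)
  outer(fv^2, fu^2, `+`)
}

# unbiased variances of matrix columns
colVars <- function(x) {
  n <- nrow(x)
  (colSums(x * x) - n * colMeans(x)^2) / (n - 1)
}

# accept either a SamplingSegment or a bare numeric vector
segValues <- function(x) {
  if (is(x, "SamplingSegment")) x@values
  else if (is.numeric(x)) x
  else stop("expected a SamplingSegment or a numeric vector")
}

segChannel <- function(x) {
  if (is(x, "SamplingSegment")) x@channel else NA_character_
}

checkSameChannel <- function(a, b) {
  ca <- segChannel(a); cb <- segChannel(b)
  if (!is.na(ca) && !is.na(cb) && ca != cb)
    stop("segments come from different channels ('", ca, "' vs '", cb, "')")
  invisible(TRUE)
}
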