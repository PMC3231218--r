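# Independent oracles and small fixture builders used across the suite.

# Brute-force Fresnel propagation: dense DFT matrices and a loop-built
# transfer function (no fft(), no shared grid code) — an O(N^4) independent
# path against the package's FFT implementation.
oracleDFTmat <- function(N) exp(-2i * pi * outer(0:(N - 1), 0:(N - 1)) / N)

oraclePropagate <- function(x, distance, optics) {
  ny <- nrow(x); nx <- ncol(x)
  Wy <- oracleDFTmat(ny); Wx <- oracleDFTmat(nx)
  Fx <- Wy %*% x %*% Wx
  H <- matrix(0 + 0i, ny, nx)
  for (r in seq_len(ny)) {
    for (c in seq_len(nx)) {
      v <- r - 1; if (v >= ny / 2) v <- v - ny
      u <- c - 1; if (u >= nx / 2) u <- u - nx
      fu <- u / (nx * optics@pixelPitch[1])
      fv <- v / (ny * optics@pixelPitch[2])
      H[r, c] <- exp(-1i * pi * optics@wavelength * distance * (fu^2 + fv^2))
    }
  }
  (Conj(Wy) %*% (Fx * H) %*% Conj(Wx)) / (nx * ny)
}

relRMS <- function(a, b) {
  sqrt(mean(Mod(a - b)^2)) / sqrt(mean(Mod(b)^2))
}

# chessboard dilation used to score segmentation leakage
dilateBy <- function(mask, r) {
  ny <- nrow(mask); nx <- ncol(mask)
  out <- mask
  for (dr in -r:r) for (dc in -r:r) {
    ri <- pmin(pmax(seq_len(ny) + dr, 1L), ny)
    ci <- pmin(pmax(seq_len(nx) + dc, 1L), nx)
    out <- out | mask[ri, ci]
  }
  out
}

randomComplexField <- function(optics, seed = 1) {
  n <- prod(optics@dims)
  set.seed(seed)
  complexField(matrix(complex(real = rnorm(n), imaginary = rnorm(n)),
                      optics@dims[1], optics@dims[2]), optics)
}

# desk-scale optics for unit tests (avoids rebuilding everywhere)
testOptics <- function(dims = 256L) opticalSetup(dims = dims,
                                                 pixelPitch = 0.3e-6)

testShape <- function(class, dims = 256L) {
  if (dims >= 256L) {
    if (class == "filament") list(length = 40e-6)
    else list(semiMajor = 8e-6, semiMinor = 5e-6)
  } else {
    if (class == "filament") list(length = 18e-6, width = 3e-6)
    else list(semiMajor = 5e-6, semiMinor = 3e-6)
  }
}

# simulate -> record -> reconstruct one desk-scale specimen
testReconstruction <- function(class = "filament", seed = 1,
                               phaseDispersion = 0.3, dims = 256L) {
  obj <- simulateSpecimen(class, testOptics(dims),
                          phaseDispersion = phaseDispersion,
                          shapeParams = testShape(class, dims), seed = seed)
  list(object = obj, field = reconstructField(recordHologram(obj)))
}
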