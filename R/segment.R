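# Target-window segmentation of the reconstructed amplitude image:
# Gaussian smoothing -> Sobel gradient -> dual-quantile markers ->
# marker-controlled watershed -> hole filling and small-object removal.

# circular (FFT) Gaussian smoothing; sigma in pixels, unit DC gain
gaussianSmooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  ny <- nrow(x); nx <- ncol(x)
  fu <- fftIndex(nx) / nx
  fv <- fftIndex(ny) / ny
  G <- exp(-2 * pi^2 * sigma^2 * outer(fv^2, fu^2, `+`))
  Re(stats::fft(stats::fft(x) * G, inverse = TRUE)) / (nx * ny)
}

# shift with edge replication
shiftMat <- function(x, dr, dc) {
  ny <- nrow(x); nx <- ncol(x)
  ri <- pmin(pmax(seq_len(ny) + dr, 1L), ny)
  ci <- pmin(pmax(seq_len(nx) + dc, 1L), nx)
  x[ri, ci, drop = FALSE]
}

sobelGradient <- function(x) {
  gx <- (shiftMat(x, -1, 1) + 2 * shiftMat(x, 0, 1) + shiftMat(x, 1, 1) -
         shiftMat(x, -1, -1) - 2 * shiftMat(x, 0, -1) - shiftMat(x, 1, -1)) / 8
  gy <- (shiftMat(x, 1, -1) + 2 * shiftMat(x, 1, 0) + shiftMat(x, 1, 1) -
         shiftMat(x, -1, -1) - 2 * shiftMat(x, -1, 0) - shiftMat(x, -1, 1)) / 8
  sqrt(gx^2 + gy^2)
}

# binary dilation by a chessboard radius (shift-OR)
dilateMask <- function(mask, radius) {
  out <- mask
  for (dr in -radius:radius)
    for (dc in -radius:radius)
      if (dr != 0 || dc != 0) out <- out | shiftMat(mask, dr, dc)
  out
}

fillHoles <- function(mask) {
  comp <- cpp_label(!mask, 4L)
  border <- unique(c(comp[1, ], comp[nrow(comp), ], comp[, 1], comp[, ncol(comp)]))
  border <- border[border > 0]
  holes <- comp > 0 & !(comp %in% border)
  mask | holes
}

removeSmall <- function(mask, minArea) {
  if (!any(mask)) return(mask)
  comp <- cpp_label(mask, 8L)
  sizes <- tabulate(comp[comp > 0])
  keep <- which(sizes >= minArea)
  matrix(comp %in% keep, nrow(mask), ncol(mask))
}

#' Segment the specimen target window from a reconstructed field
#'
#' Marker-controlled watershed on the gradient of the smoothed amplitude
#' image. Background markers are pixels below the `bgQuantile` amplitude
#' quantile; foreground markers are connected components of pixels above the
#' `fgQuantile` quantile (components smaller than `minMarkerArea` pixels are
#' discarded as residual twin-image haze). The basins grown from foreground
#' markers, after hole filling and removal of components below `minArea`,
#' form the binary target window.
#'
#' The amplitude channel is segmented: for semitransparent phase specimens
#' the scattered-wave modulus is the natural contrast carrier, and the
#' defocused conjugate (twin) residue is much weaker than the focused image.
#'
#' @param field a [ComplexField-class] (or a numeric amplitude matrix).
#' @param smoothSigma Gaussian smoothing scale in pixels (default 1.5; large
#'   enough to suppress speckle from the specimen's internal phase noise,
#'   small enough not to drag the watershed line onto the first diffraction
#'   fringe outside the specimen edge).
#' @param bgQuantile amplitude quantile below which pixels seed the
#'   background marker (default 0.25).
#' @param fgQuantile amplitude quantile above which pixels seed foreground
#'   markers (default 0.995).
#' @param minArea minimum object area in pixels kept in the final mask
#'   (default 50).
#' @param minMarkerArea minimum foreground marker component size (default 25).
#' @return a [TargetMask-class]; `x@params` logs every parameter used.
#' @export
#' @examples
#' amp <- matrix(0.1, 128, 128)
#' amp[40:80, 50:90][outer((-20:20)^2, (-20:20)^2, "+") <= 15^2] <- 1
#' m <- segmentTarget(amp)
#' sum(maskMatrix(m))
segmentTarget <- function(field, smoothSigma = 1.5, bgQuantile = 0.25,
                          fgQuantile = 0.995, minArea = 50,
                          minMarkerArea = 25) {
  amp <- if (is(field, "ComplexField")) amplitude(field)
         else if (is.numeric(field)) field
         else stop("'field' must be a ComplexField or a numeric matrix")
  if (any(!is.finite(amp))) stop("field has non-finite values")
  smoothed <- gaussianSmooth(amp, smoothSigma)
  qs <- stats::quantile(smoothed, c(bgQuantile, fgQuantile), names = FALSE)
  if (qs[1] >= qs[2])
    stop("no target found: amplitude image has no foreground contrast")
  # inclusive comparisons with a tiny tolerance so piecewise-constant
  # images (quantile exactly at a plateau value, plateau jittered at
  # the ringing of the FFT smoothing) still yield markers
  tol <- 1e-6 * (qs[2] - qs[1])
  fg <- smoothed >= qs[2] - tol
  # markers: label 1 = background, labels >= 2 = candidate objects
  fgcomp <- cpp_label(fg, 8L)
  sizes <- tabulate(fgcomp[fgcomp > 0])
  keep <- which(sizes >= minMarkerArea)
  if (length(keep) == 0L)
    stop("no target found: all foreground markers below 'minMarkerArea'")
  markers <- matrix(0L, nrow(amp), ncol(amp))
  markers[smoothed <= qs[1] + tol] <- 1L
  idx <- fgcomp %in% keep
  markers[idx] <- match(fgcomp[idx], keep) + 1L
  grad <- sobelGradient(smoothed)
  basins <- cpp_watershed(grad, markers)
  mask <- basins >= 2L
  mask <- fillHoles(mask)
  mask <- removeSmall(mask, minArea)
  if (!any(mask))
    stop("no target found: nothing left after the minimum-area filter")
  new("TargetMask", mask = mask, nPixels = sum(mask), channel = "amplitude",
      params = list(smoothSigma = smoothSigma, bgQuantile = bgQuantile,
                    fgQuantile = fgQuantile, minArea = minArea,
                    minMarkerArea = minMarkerArea, channel = "amplitude"))
}
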