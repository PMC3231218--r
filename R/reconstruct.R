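#' Reconstruct the complex object field from a Gabor hologram
#'
#' Inverse Fresnel transform by the angular-spectrum method with two Fourier
#' transforms: \deqn{O(x',y') = \mathrm{IFT}\{\mathrm{FT}\{I(x,y)\} \cdot
#' \exp(j\pi\lambda d_0 [u^2/(\Delta_x N_x)^2 + v^2/(\Delta_y N_y)^2])\}}
#' which cancels any scale factor between input and output grids (output has
#' the hologram's size). The zero-order (DC) background \eqn{A_r^2} dominates
#' the hologram; with `dcSuppression = "subtract_mean"` (default) the mean
#' intensity is removed before back-propagation. No explicit twin-image
#' removal is performed: when the detector captures many fringes the
#' defocused conjugate term is weak, and what remains is handled downstream
#' by segmentation.
#'
#' The full complex field is returned (never just the amplitude) because the
#' statistical recognition tests operate on the real and imaginary channels
#' separately.
#'
#' @param hologram a [Hologram-class], or a numeric intensity matrix if
#'   `optics` is supplied.
#' @param distance reconstruction distance \eqn{d_0} in metres; defaults to
#'   the recording setup's distance.
#' @param dcSuppression `"subtract_mean"` (default) or `"none"` (exact
#'   linearity in the intensity, useful for analysis).
#' @param pad if TRUE, zero-pad to twice the grid before the transforms to
#'   suppress wrap-around at the edges (slower; default FALSE).
#' @param optics an [OpticalSetup-class] when `hologram` is a bare matrix.
#' @return a [ComplexField-class] at `planeZ = distance`.
#' @seealso [forwardPropagate], [segmentTarget]
#' @export
#' @examples
#' cfg <- opticalSetup(dims = 128, pixelPitch = 0.3e-6)
#' obj <- simulateSpecimen("ellipse", cfg, phaseDispersion = 0.4,
#'   shapeParams = list(semiMajor = 6e-6, semiMinor = 4e-6), seed = 2)
#' fld <- reconstructField(recordHologram(obj))
#' range(amplitude(fld))
reconstructField <- function(hologram, distance = NULL,
                             dcSuppression = c("subtract_mean", "none"),
                             pad = FALSE, optics = NULL) {
  dcSuppression <- match.arg(dcSuppression)
  if (is(hologram, "Hologram")) {
    optics <- hologram@optics
    intens <- hologram@intensity
  } else {
    if (is.null(optics)) stop("'optics' required when passing a bare matrix")
    intens <- hologram
  }
  if (any(!is.finite(intens))) stop("hologram intensity has non-finite values")
  if (is.null(distance)) distance <- optics@distance
  if (dcSuppression == "subtract_mean") intens <- intens - mean(intens)
  if (pad) {
    ny <- optics@dims[1]; nx <- optics@dims[2]
    big <- opticalSetup(optics@wavelength, optics@pixelPitch,
                        dims = c(2L * ny, 2L * nx), distance = optics@distance)
    buf <- matrix(0, 2L * ny, 2L * nx)
    i0 <- ny %/% 2; j0 <- nx %/% 2
    buf[i0 + seq_len(ny), j0 + seq_len(nx)] <- intens
    out <- forwardPropagate(buf, -distance, optics = big)@values
    vals <- out[i0 + seq_len(ny), j0 + seq_len(nx)]
    return(complexField(vals, optics, planeZ = distance))
  }
  # back-propagation: transfer-function exponent +j pi lambda d0 [.]
  fld <- forwardPropagate(intens, -distance, optics = optics)
  complexField(fld@values, optics, planeZ = distance)
}
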