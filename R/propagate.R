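#' Fresnel propagation by the angular-spectrum transfer function
#'
#' Propagates a complex field over an axial distance using the paraxial
#' (Fresnel) transfer function applied in the frequency domain with two
#' FFTs: \deqn{U_d = \mathrm{IFT}\{ \mathrm{FT}\{U_0\} \cdot
#' e^{-j\pi\lambda d\,[u^2/(N_x\Delta x)^2 + v^2/(N_y\Delta y)^2]} \}}
#' where \eqn{u, v} are zero-centred discrete frequencies. The transfer
#' function has unit modulus, so total power is conserved exactly and
#' propagation over \eqn{-d} is the exact inverse of propagation over
#' \eqn{+d}. The sign convention is chosen so that *reconstruction*
#' (back-propagation, negative distance here) carries the positive
#' exponent \eqn{+j\pi\lambda d_0 [\dots]}; see [reconstructField].
#'
#' @param field a [ComplexField-class], or a (complex or numeric) matrix if
#'   `optics` is supplied.
#' @param distance propagation distance in metres; negative values
#'   back-propagate; 0 returns the input unchanged.
#' @param optics an [OpticalSetup-class]; defaults to `optics(field)` when
#'   `field` is a ComplexField.
#' @return a [ComplexField-class] at plane `planeZ + distance`.
#' @seealso [reconstructField]
#' @export
#' @examples
#' cfg <- opticalSetup(dims = 64, pixelPitch = 0.3e-6)
#' pt <- matrix(0 + 0i, 64, 64); pt[32, 32] <- 1 + 0i
#' f0 <- complexField(pt, cfg)
#' f1 <- forwardPropagate(f0, 25e-6)
#' sum(Mod(fieldValues(f1))^2)  # power conserved: 1
forwardPropagate <- function(field, distance, optics = NULL) {
  if (is(field, "ComplexField")) {
    if (is.null(optics)) optics <- field@optics
    vals <- field@values
    z0 <- field@planeZ
  } else {
    if (is.null(optics)) stop("'optics' is required when 'field' is a matrix")
    vals <- field
    if (!is.complex(vals)) storage.mode(vals) <- "complex"
    z0 <- 0
  }
  if (!identical(dim(vals), as.integer(optics@dims)))
    stop("field dimensions do not match the optical setup")
  if (distance == 0)
    return(complexField(vals, optics, planeZ = z0))
  H <- exp(-1i * pi * optics@wavelength * distance * freqSqGrid(optics))
  out <- stats::fft(stats::fft(vals) * H, inverse = TRUE) / length(vals)
  complexField(out, optics, planeZ = z0 + distance)
}
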