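#' Construct an optical recording geometry
#'
#' Defaults follow a typical Gabor holographic microscope: argon-ion line at
#' 514.5 nm, a 2048 x 2048 sensor with 9 um pixels and a 25 um
#' recording/reconstruction distance. For desk-scale synthetic work pass a
#' smaller grid and the *effective* pixel pitch at the object plane (the
#' objective's magnification divides the detector pitch; 9 um / 30x = 0.3 um
#' is the package's synthetic default).
#'
#' A warning (not an error) is emitted if the pixel pitch falls below half
#' the wavelength: the grid then carries spatial frequencies that are
#' evanescent in reality, outside the validity of the paraxial Fresnel
#' transfer function.
#'
#' @param wavelength wavelength in metres.
#' @param pixelPitch pixel pitch in metres; length 1 (square pixels) or 2.
#' @param dims grid size; length 1 (square grid) or 2 as (Ny, Nx).
#' @param distance default propagation/reconstruction distance in metres
#'   (used when an operation is not given an explicit distance).
#' @return an [OpticalSetup-class] object.
#' @export
#' @examples
#' opticalSetup(dims = 512, pixelPitch = 0.3e-6)
opticalSetup <- function(wavelength = 514.5e-9,
                         pixelPitch = 9e-6,
                         dims = c(2048L, 2048L),
                         distance = 25e-6) {
  if (length(pixelPitch) == 1L) pixelPitch <- rep(pixelPitch, 2L)
  if (length(dims) == 1L) dims <- rep(dims, 2L)
  obj <- new("OpticalSetup",
    wavelength = as.numeric(wavelength),
    pixelPitch = as.numeric(pixelPitch),
    dims = as.integer(dims),
    distance = as.numeric(distance))
  if (min(obj@pixelPitch) < obj@wavelength / 2)
    warning("pixel pitch below half the wavelength: the grid supports ",
            "evanescent spatial frequencies and the paraxial (Fresnel) ",
            "propagation model may be inaccurate")
  obj
}

#' Construct a complex field
#'
#' @param values complex (or numeric, promoted) matrix.
#' @param optics an [OpticalSetup-class]; its dims must match `values`.
#' @param planeZ axial plane of the field in metres.
#' @return a [ComplexField-class].
#' @export
complexField <- function(values, optics, planeZ = 0) {
  if (!is.complex(values)) storage.mode(values) <- "complex"
  new("ComplexField", values = values, optics = optics,
      planeZ = as.numeric(planeZ))
}
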