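#' Record a Gabor in-line hologram of a phase object
#'
#' Implements the single-exposure in-line recording model. The specimen is a
#' thin phase screen with complex transmission \eqn{t = e^{j\phi(x,y)}}; the
#' unscattered (ballistic) component passes through unchanged and acts as the
#' reference wave, while the scattered component \eqn{t - 1} propagates over
#' the recording distance \eqn{d} to the hologram plane, giving the object
#' wave \eqn{O_h = A_h e^{j\phi_h}}. The detector records
#' \deqn{I(x,y) = |A_r e^{j\phi_r} + O_h(x,y)|^2
#'   = A_h^2 + A_r^2 + 2 A_h A_r \cos(\phi_h - \phi_r),}
#' optionally with additive Gaussian read noise (clipped at zero). The
#' weak-object assumption \eqn{|A_h| \ll A_r} justifies neglecting the
#' \eqn{A_h^2} term at reconstruction time; the realised ratio
#' \eqn{\max|A_h|/A_r} is reported in the metadata so its validity can be
#' checked per recording.
#'
#' @param object a [PhaseObject-class].
#' @param refAmplitude reference wave amplitude \eqn{A_r > 0}.
#' @param refPhase constant reference phase \eqn{\phi_r} in radians.
#' @param noiseSigma std of additive Gaussian intensity noise (>= 0;
#'   default 0: the recording model itself is noise-free).
#' @param distance recording distance in metres; defaults to the distance of
#'   the object's optical setup.
#' @param seed integer seed (only consumed when `noiseSigma > 0`).
#' @return a [Hologram-class]; `x@meta$weakObjectRatio` holds
#'   \eqn{\max|A_h|/A_r}.
#' @export
#' @examples
#' cfg <- opticalSetup(dims = 128, pixelPitch = 0.3e-6)
#' obj <- simulateSpecimen("ellipse", cfg, phaseDispersion = 0.4,
#'   shapeParams = list(semiMajor = 6e-6, semiMinor = 4e-6), seed = 2)
#' h <- recordHologram(obj)
#' mean(holoIntensity(h))
recordHologram <- function(object, refAmplitude = 1, refPhase = 0,
                           noiseSigma = 0, distance = NULL, seed = 1L) {
  stopifnot(is(object, "PhaseObject"))
  if (refAmplitude <= 0) stop("'refAmplitude' must be positive")
  if (noiseSigma < 0) stop("'noiseSigma' must be >= 0")
  cfg <- object@optics
  if (is.null(distance)) distance <- cfg@distance
  scattered <- exp(1i * object@phaseMap) - 1  # zero outside the support
  oh <- forwardPropagate(scattered, distance, optics = cfg)@values
  ref <- refAmplitude * exp(1i * refPhase)
  intens <- Mod(ref + oh)^2
  if (noiseSigma > 0) {
    intens <- withSeed(seed,
      intens + stats::rnorm(length(intens), 0, noiseSigma))
    intens <- pmax(matrix(intens, nrow(oh), ncol(oh)), 0)
  }
  new("Hologram", intensity = intens, optics = cfg,
      refAmplitude = as.numeric(refAmplitude),
      refPhase = as.numeric(refPhase),
      meta = list(
        weakObjectRatio = max(Mod(oh)) / refAmplitude,
        noiseSigma = noiseSigma,
        distance = distance,
        classLabel = object@classLabel))
}
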