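#' @import methods
NULL

#' Optical recording geometry for an in-line (Gabor) hologram
#'
#' Holds the illumination wavelength, detector pixel pitch, sensor grid size
#' and the default recording/reconstruction distance. The microscope
#' objective of a physical bench is not modelled explicitly: its transverse
#' magnification is absorbed into an *effective* pixel pitch at the object
#' plane, so `pixelPitch` should be interpreted at the plane of the specimen.
#'
#' @slot wavelength numeric(1), illumination wavelength in metres.
#' @slot pixelPitch numeric(2), effective pixel pitch (dx, dy) in metres.
#' @slot dims integer(2), grid size (Ny rows, Nx columns).
#' @slot distance numeric(1), default propagation/reconstruction distance
#'   between object plane and hologram plane, in metres.
#' @aliases OpticalSetup-class
#' @exportClass OpticalSetup
setClass("OpticalSetup",
  representation(
    wavelength = "numeric",
    pixelPitch = "numeric",
    dims       = "integer",
    distance   = "numeric"
  )
)

setValidity("OpticalSetup", function(object) {
  msg <- character()
  if (length(object@wavelength) != 1L || !is.finite(object@wavelength) ||
      object@wavelength <= 0)
    msg <- c(msg, "'wavelength' must be a single positive number")
  if (length(object@pixelPitch) != 2L || any(!is.finite(object@pixelPitch)) ||
      any(object@pixelPitch <= 0))
    msg <- c(msg, "'pixelPitch' must be two positive numbers (dx, dy)")
  if (length(object@dims) != 2L || any(is.na(object@dims)) ||
      any(object@dims < 8L))
    msg <- c(msg, "'dims' must be two integers >= 8 (Ny, Nx)")
  if (length(object@distance) != 1L || !is.finite(object@distance) ||
      object@distance <= 0)
    msg <- c(msg, "'distance' must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' A complex optical field sampled on a regular grid
#'
#' Two-dimensional grid of complex values (amplitude and phase) at a stated
#' axial plane. The real and imaginary channels of a reconstructed field are
#' the quantities subjected to the statistical sampling tests.
#'
#' @slot values complex matrix, dimensions `dims(optics)`.
#' @slot planeZ numeric(1), axial position of the plane in metres (0 = the
#'   object plane).
#' @slot optics an [OpticalSetup-class] object.
#' @aliases ComplexField-class
#' @exportClass ComplexField
setClass("ComplexField",
  representation(
    values = "matrix",
    planeZ = "numeric",
    optics = "OpticalSetup"
  )
)

setValidity("ComplexField", function(object) {
  msg <- character()
  if (!is.complex(object@values))
    msg <- c(msg, "'values' must be a complex matrix")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "'values' must be finite")
  if (!identical(dim(object@values), as.integer(object@optics@dims)))
    msg <- c(msg, "dim(values) must equal dims of the optical setup (Ny, Nx)")
  if (length(object@planeZ) != 1L || !is.finite(object@planeZ))
    msg <- c(msg, "'planeZ' must be a single finite number")
  if (length(msg)) msg else TRUE
})

#' A synthetic specimen modelled as a thin phase screen
#'
#' Semitransparent micro-specimens delay the transmitted wavefront by an
#' optical path difference that depends on local thickness and refractive
#' index; the volumetric object is collapsed to a single effective phase
#' screen at the object plane. The phase map is zero outside the support.
#'
#' @slot phaseMap numeric matrix of phase delays in radians.
#' @slot support logical matrix, TRUE where the specimen is present.
#' @slot axialExtent numeric(1), nominal specimen thickness in metres
#'   (informational; the screen is thin).
#' @slot classLabel character(1), specimen class identifier.
#' @slot optics an [OpticalSetup-class].
#' @aliases PhaseObject-class
#' @exportClass PhaseObject
setClass("PhaseObject",
  representation(
    phaseMap    = "matrix",
    support     = "matrix",
    axialExtent = "numeric",
    classLabel  = "character",
    optics      = "OpticalSetup"
  )
)

setValidity("PhaseObject", function(object) {
  msg <- character()
  if (!is.numeric(object@phaseMap))
    msg <- c(msg, "'phaseMap' must be numeric")
  if (!is.logical(object@support))
    msg <- c(msg, "'support' must be logical")
  if (!identical(dim(object@phaseMap), dim(object@support)))
    msg <- c(msg, "'phaseMap' and 'support' dims differ")
  if (!any(object@support))
    msg <- c(msg, "'support' must be nonempty")
  if (any(object@phaseMap[!object@support] != 0))
    msg <- c(msg, "'phaseMap' must be zero outside the support")
  if (object@axialExtent < 0)
    msg <- c(msg, "'axialExtent' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' A recorded in-line hologram
#'
#' Nonnegative real intensity \eqn{I(x,y) = |R + O_h|^2}: the interference of
#' a plane reference wave \eqn{R = A_r e^{j\phi_r}} (the unscattered,
#' ballistic component of the illumination) with the scattered object wave
#' \eqn{O_h} propagated to the detector plane.
#'
#' @slot intensity numeric matrix of nonnegative intensities.
#' @slot optics an [OpticalSetup-class].
#' @slot refAmplitude numeric(1), reference wave amplitude \eqn{A_r > 0}.
#' @slot refPhase numeric(1), constant reference phase \eqn{\phi_r} (rad).
#' @slot meta list of recording metadata (weak-object ratio, noise level,
#'   specimen class).
#' @aliases Hologram-class
#' @exportClass Hologram
setClass("Hologram",
  representation(
    intensity    = "matrix",
    optics       = "OpticalSetup",
    refAmplitude = "numeric",
    refPhase     = "numeric",
    meta         = "list"
  )
)

setValidity("Hologram", function(object) {
  msg <- character()
  if (!is.numeric(object@intensity) || any(!is.finite(object@intensity)))
    msg <- c(msg, "'intensity' must be a finite numeric matrix")
  if (any(object@intensity < 0))
    msg <- c(msg, "'intensity' must be nonnegative")
  if (!identical(dim(object@intensity), as.integer(object@optics@dims)))
    msg <- c(msg, "dim(intensity) must equal dims of the optical setup")
  if (length(object@refAmplitude) != 1L || object@refAmplitude <= 0)
    msg <- c(msg, "'refAmplitude' must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Binary target window isolating the specimen
#'
#' Result of watershed segmentation of the reconstructed amplitude image:
#' TRUE over the specimen ("target") region, FALSE over background and
#' residual conjugate (twin-image) haze.
#'
#' @slot mask logical matrix.
#' @slot nPixels integer(1), number of TRUE pixels.
#' @slot channel character(1), image channel segmented (\code{"amplitude"}).
#' @slot params list of the segmentation parameters actually used.
#' @aliases TargetMask-class
#' @exportClass TargetMask
setClass("TargetMask",
  representation(
    mask    = "matrix",
    nPixels = "integer",
    channel = "character",
    params  = "list"
  )
)

setValidity("TargetMask", function(object) {
  msg <- character()
  if (!is.logical(object@mask))
    msg <- c(msg, "'mask' must be logical")
  if (object@nPixels != sum(object@mask))
    msg <- c(msg, "'nPixels' must equal sum(mask)")
  if (object@nPixels <= 0L)
    msg <- c(msg, "mask must be nonempty")
  if (length(msg)) msg else TRUE
})

#' One trial sampling segment
#'
#' A set of \eqn{n} scalar values drawn (without replacement within the
#' segment) from one channel — real or imaginary part — of the masked pixels
#' of a reconstructed complex field. One segment is one statistical sample.
#'
#' @slot values numeric vector of length `n`.
#' @slot channel character(1), \code{"real"} or \code{"imaginary"}.
#' @slot n integer(1), sample size.
#' @slot sourceId character(1), identifier of the source image.
#' @slot seed integer(1), seed used for the draw (NA if not drawn by
#'   [drawSegments]).
#' @aliases SamplingSegment-class
#' @exportClass SamplingSegment
setClass("SamplingSegment",
  representation(
    values   = "numeric",
    channel  = "character",
    n        = "integer",
    sourceId = "character",
    seed     = "integer"
  )
)

setValidity("SamplingSegment", function(object) {
  msg <- character()
  if (length(object@values) != object@n)
    msg <- c(msg, "length(values) must equal n")
  if (object@n < 2L)
    msg <- c(msg, "segment must hold at least 2 values")
  if (!object@channel %in% c("real", "imaginary"))
    msg <- c(msg, "channel must be 'real' or 'imaginary'")
  if (length(msg)) msg else TRUE
})

#' Result of the two-sample variance-ratio (F) test
#'
#' @slot statistic numeric(1), \eqn{F = \hat V[r]/\hat V[s]} (unbiased sample
#'   variances).
#' @slot dof numeric(2), degrees of freedom \eqn{(n_r-1, n_s-1)}.
#' @slot variances numeric(2), the two sample variances.
#' @slot alpha numeric(1), significance level.
#' @slot acceptInterval numeric(2), two-tailed acceptance interval
#'   \eqn{[F_{\alpha/2}, F_{1-\alpha/2}]}.
#' @slot pValue numeric(1).
#' @slot pMode character(1), \code{"analytic"} or \code{"monte_carlo"}.
#' @slot decision character(1), \code{"accept_H0"} or \code{"reject_H0"}.
#' @slot ciVarianceRatio numeric(2), \eqn{1-\alpha} confidence interval for
#'   the population variance ratio \eqn{\sigma_r^2/\sigma_s^2}.
#' @aliases VarianceRatioResult-class
#' @exportClass VarianceRatioResult
setClass("VarianceRatioResult",
  representation(
    statistic       = "numeric",
    dof             = "numeric",
    variances       = "numeric",
    alpha           = "numeric",
    acceptInterval  = "numeric",
    pValue          = "numeric",
    pMode           = "character",
    decision        = "character",
    ciVarianceRatio = "numeric"
  )
)

setValidity("VarianceRatioResult", function(object) {
  msg <- character()
  if (object@statistic <= 0) msg <- c(msg, "F statistic must be positive")
  if (object@acceptInterval[1] >= object@acceptInterval[2])
    msg <- c(msg, "acceptance interval must have lower < upper")
  inside <- object@statistic >= object@acceptInterval[1] &&
    object@statistic <= object@acceptInterval[2]
  if ((object@decision == "accept_H0") != inside)
    msg <- c(msg, "decision must match F in/outside the acceptance interval")
  if (length(msg)) msg else TRUE
})

#' Result of the nonparametric ECDF discriminant test
#'
#' @slot statistic numeric(1), observed \eqn{\Lambda} (mean squared ECDF
#'   difference between reference and input segments).
#' @slot nullStatistics numeric vector of \eqn{\tilde\Lambda} values from
#'   disjoint reference-segment pairs (the Monte-Carlo null).
#' @slot pValue numeric(1), add-one upper-tail proportion.
#' @slot alpha numeric(1).
#' @slot decision character(1), \code{"accept_H0"} or \code{"reject_H0"}.
#' @aliases EcdfTestResult-class
#' @exportClass EcdfTestResult
setClass("EcdfTestResult",
  representation(
    statistic      = "numeric",
    nullStatistics = "numeric",
    pValue         = "numeric",
    alpha          = "numeric",
    decision       = "character"
  )
)

setValidity("EcdfTestResult", function(object) {
  msg <- character()
  if (object@statistic < 0 || any(object@nullStatistics < 0))
    msg <- c(msg, "Lambda statistics must be nonnegative")
  pmin_att <- 1 / (1 + length(object@nullStatistics))
  if (object@pValue < pmin_att - 1e-12 || object@pValue > 1)
    msg <- c(msg, "p-value must lie in [1/(1+n_null), 1]")
  if (length(msg)) msg else TRUE
})

#' ROC curve summary for a recognition score
#'
#' @slot thresholds numeric vector of sweep thresholds (original score scale).
#' @slot tpr numeric vector, true-positive rates.
#' @slot fpr numeric vector, false-positive rates.
#' @slot auc numeric(1), area under the curve (trapezoid rule; equals the
#'   Mann-Whitney probability with half-credit ties).
#' @slot n integer(1), sample size the scores were computed at (NA if not
#'   applicable).
#' @aliases RocResult-class
#' @exportClass RocResult
setClass("RocResult",
  representation(
    thresholds = "numeric",
    tpr        = "numeric",
    fpr        = "numeric",
    auc        = "numeric",
    n          = "integer"
  )
)

setValidity("RocResult", function(object) {
  msg <- character()
  if (object@auc < 0 || object@auc > 1) msg <- c(msg, "auc must be in [0,1]")
  if (is.unsorted(object@tpr) || is.unsorted(object@fpr))
    msg <- c(msg, "tpr and fpr must be monotone along the sweep")
  if (length(msg)) msg else TRUE
})

#' End-to-end recognition experiment configuration
#'
#' @slot optics an [OpticalSetup-class] (the desk-scale default uses a
#'   512x512 grid with 0.25 um effective pitch).
#' @slot classes list of specimen specs; each a list with elements `label`,
#'   `phaseDispersion` (rad) and optionally `phaseMean`, `shapeParams`.
#' @slot n integer(1), pixels per sampling segment (default 200).
#' @slot m integer(1), trial segments per experiment (default 100).
#' @slot alpha numeric(1), significance level (default 0.01).
#' @slot tests character, subset of c("f", "ks").
#' @slot sampleSizes integer vector of segment sizes for the ROC sweep.
#' @slot nNull integer(1), number of disjoint reference-segment pairs used
#'   for the ECDF-test null distribution.
#' @slot noiseSigma numeric(1), additive intensity noise std (default 0).
#' @slot seed integer(1), master seed.
#' @aliases ExperimentConfig-class
#' @exportClass ExperimentConfig
setClass("ExperimentConfig",
  representation(
    optics      = "OpticalSetup",
    classes     = "list",
    n           = "integer",
    m           = "integer",
    alpha       = "numeric",
    tests       = "character",
    sampleSizes = "integer",
    nNull       = "integer",
    noiseSigma  = "numeric",
    seed        = "integer"
  )
)

setValidity("ExperimentConfig", function(object) {
  msg <- character()
  if (length(object@classes) < 2L)
    msg <- c(msg, "at least 2 specimen classes are required for recognition")
  if (object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must be in (0, 1)")
  if (!all(object@tests %in% c("f", "ks")))
    msg <- c(msg, "tests must be a subset of c('f', 'ks')")
  if (object@n < 2L || object@m < 1L)
    msg <- c(msg, "need n >= 2 and m >= 1")
  if (length(msg)) msg else TRUE
})
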