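# Synthetic specimen generator: compact phase objects standing in for
# semitransparent microorganisms (filamentous cyanobacteria vs. patterned
# elliptical diatom-like algae). Classes differ in support geometry and,
# crucially, in the dispersion of their optical-path-difference (phase)
# distribution — the feature the downstream statistical tests exploit.

# ---- shape registry ---------------------------------------------------------

# each entry: function(optics, shapeParams, rng already seeded) -> logical
# support matrix + list of deterministic phase offsets (pattern), plus the
# resolved parameter list for logging
.drawFilamentSupport <- function(optics, p) {
  ny <- optics@dims[1]; nx <- optics@dims[2]
  dx <- optics@pixelPitch[1]; dy <- optics@pixelPitch[2]
  L <- p$length; w <- p$width
  ds <- min(dx, dy) / 2
  s <- seq(0, L, by = ds)
  # tangent angle varies slowly along arc length -> gently curved ribbon of
  # exact arc length L
  theta0 <- stats::runif(1, 0, 2 * pi)
  theta <- theta0 + p$wiggle * sin(2 * pi * p$cycles * s / L)
  cx <- (nx / 2 + stats::runif(1, -0.05, 0.05) * nx) * dx
  cy <- (ny / 2 + stats::runif(1, -0.05, 0.05) * ny) * dy
  xs <- cx + c(0, cumsum(cos(theta[-1]) * ds)) - sum(cos(theta)) * ds / 2
  ys <- cy + c(0, cumsum(sin(theta[-1]) * ds)) - sum(sin(theta)) * ds / 2
  sup <- matrix(FALSE, ny, nx)
  rpx <- w / 2 / dx; rpy <- w / 2 / dy
  for (k in seq_along(xs)) {
    j0 <- max(1, floor(xs[k] / dx - rpx)); j1 <- min(nx, ceiling(xs[k] / dx + rpx))
    i0 <- max(1, floor(ys[k] / dy - rpy)); i1 <- min(ny, ceiling(ys[k] / dy + rpy))
    if (j0 > j1 || i0 > i1) next
    jj <- j0:j1; ii <- i0:i1
    d2 <- outer(((ii - 0.5) * dy - ys[k])^2, ((jj - 0.5) * dx - xs[k])^2, `+`)
    sup[ii, jj] <- sup[ii, jj] | (d2 <= (w / 2)^2)
  }
  list(support = sup, pattern = NULL)
}

.drawEllipseSupport <- function(optics, p) {
  ny <- optics@dims[1]; nx <- optics@dims[2]
  dx <- optics@pixelPitch[1]; dy <- optics@pixelPitch[2]
  a <- p$semiMajor; b <- p$semiMinor
  phi <- stats::runif(1, 0, pi)
  cx <- (nx / 2 + stats::runif(1, -0.05, 0.05) * nx) * dx
  cy <- (ny / 2 + stats::runif(1, -0.05, 0.05) * ny) * dy
  x <- ((seq_len(nx)) - 0.5) * dx - cx
  y <- ((seq_len(ny)) - 0.5) * dy - cy
  X <- matrix(x, ny, nx, byrow = TRUE)
  Y <- matrix(y, ny, nx)
  Xr <- X * cos(phi) + Y * sin(phi)
  Yr <- -X * sin(phi) + Y * cos(phi)
  sup <- (Xr / a)^2 + (Yr / b)^2 <= 1
  # diatom-like striae: deterministic phase modulation across the major axis
  pattern <- NULL
  if (p$patternDepth > 0)
    pattern <- p$patternDepth * cos(2 * pi * Xr / p$patternPeriod)
  list(support = sup, pattern = pattern)
}

.specimenRegistry <- list(
  filament = list(
    draw = .drawFilamentSupport,
    defaults = list(length = 80e-6, width = 5e-6, wiggle = 0.25, cycles = 2)
  ),
  ellipse = list(
    draw = .drawEllipseSupport,
    defaults = list(semiMajor = 15e-6, semiMinor = 10e-6,
                    patternDepth = 0.2, patternPeriod = 2e-6)
  )
)

#' Generate a synthetic phase-object specimen
#'
#' Builds a thin phase screen with class-specific support geometry — a
#' curved filament ribbon (`"filament"`) or a patterned ellipse
#' (`"ellipse"`) — and fills the support with phase values drawn i.i.d.
#' from \eqn{N(\mu_\phi, \sigma_\phi^2)}, where \eqn{\sigma_\phi} is the
#' class's characteristic phase dispersion. Phase is zero outside the
#' support. Deterministic for a fixed seed.
#'
#' @param class specimen class label; one of the registered classes
#'   `"filament"` or `"ellipse"`.
#' @param optics an [OpticalSetup-class] giving the grid and effective
#'   object-plane pixel pitch.
#' @param phaseDispersion standard deviation of the phase inside the support,
#'   in radians (>= 0; 0 gives a constant phase screen).
#' @param phaseMean mean phase delay inside the support, radians.
#' @param shapeParams named list overriding the class's geometric defaults
#'   (filament: `length`, `width`, `wiggle`, `cycles`; ellipse: `semiMajor`,
#'   `semiMinor`, `patternDepth`, `patternPeriod`; lengths in metres).
#' @param axialExtent nominal specimen thickness in metres (informational).
#' @param seed integer seed.
#' @return a [PhaseObject-class].
#' @export
#' @examples
#' cfg <- opticalSetup(dims = 256, pixelPitch = 0.3e-6)
#' obj <- simulateSpecimen("filament", cfg, phaseDispersion = 0.3,
#'                         shapeParams = list(length = 40e-6), seed = 1)
#' sum(support(obj))
simulateSpecimen <- function(class, optics,
                             phaseDispersion = 0.5,
                             phaseMean = 1.0,
                             shapeParams = list(),
                             axialExtent = 5e-6,
                             seed = 1L) {
  if (!class %in% names(.specimenRegistry))
    stop("unknown specimen class '", class, "'; registered classes: ",
         paste(names(.specimenRegistry), collapse = ", "))
  if (phaseDispersion < 0) stop("'phaseDispersion' must be >= 0")
  entry <- .specimenRegistry[[class]]
  p <- utils::modifyList(entry$defaults, shapeParams)
  withSeed(seed, {
    geom <- entry$draw(optics, p)
    sup <- geom$support
    if (!any(sup))
      stop("specimen support is empty at this grid; enlarge the shape or ",
           "refine the pixel pitch")
    phase <- matrix(0, nrow(sup), ncol(sup))
    npix <- sum(sup)
    phase[sup] <- phaseMean + stats::rnorm(npix, 0, phaseDispersion)
    if (!is.null(geom$pattern)) phase[sup] <- phase[sup] + geom$pattern[sup]
    new("PhaseObject", phaseMap = phase, support = sup,
        axialExtent = as.numeric(axialExtent), classLabel = class,
        optics = optics)
  })
}

#' Registered specimen classes
#' @return character vector of class labels known to [simulateSpecimen].
#' @export
specimenClasses <- function() names(.specimenRegistry)
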