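# Statistical sampling inference on the masked reconstructed field:
# random trial segments, the parametric variance-ratio (F) test and the
# nonparametric ECDF discriminant statistic with a Monte-Carlo null.

#' Construct a sampling segment from bare values
#'
#' @param values numeric vector (length >= 2).
#' @param channel `"real"` or `"imaginary"`.
#' @param sourceId identifier of the source image.
#' @param seed integer seed used for the draw, or NA.
#' @return a [SamplingSegment-class].
#' @export
samplingSegment <- function(values, channel = "real", sourceId = "manual",
                            seed = NA_integer_) {
  new("SamplingSegment", values = as.numeric(values), channel = channel,
      n = length(values), sourceId = sourceId, seed = as.integer(seed))
}

#' Draw random trial sampling segments from a masked field
#'
#' Randomly extracts `n` pixels `m` times from the segmented region of a
#' reconstructed complex image. Within one segment pixels are sampled
#' without replacement (each pixel is a distinct site); different segments
#' are drawn independently, so they may overlap. Reproducible for a fixed
#' seed.
#'
#' @param field a [ComplexField-class].
#' @param mask a [TargetMask-class] (or a logical matrix).
#' @param n pixels per segment.
#' @param m number of segments.
#' @param channel `"real"` or `"imaginary"` part of the complex image.
#' @param seed integer seed.
#' @param sourceId identifier stored in each segment.
#' @return list of `m` [SamplingSegment-class] objects.
#' @export
#' @examples
#' cfg <- opticalSetup(dims = 64, pixelPitch = 0.3e-6)
#' fld <- complexField(matrix(complex(real = rnorm(64^2),
#'   imaginary = rnorm(64^2)), 64, 64), cfg)
#' segs <- drawSegments(fld, matrix(TRUE, 64, 64), n = 50, m = 3,
#'                      channel = "real", seed = 7)
#' length(segs)
drawSegments <- function(field, mask, n, m,
                         channel = c("real", "imaginary"),
                         seed = 1L, sourceId = "field") {
  channel <- match.arg(channel)
  mk <- if (is(mask, "TargetMask")) mask@mask else mask
  vals <- fieldValues(field)
  if (!identical(dim(mk), dim(vals))) stop("mask and field dims differ")
  idx <- which(mk)
  if (n > length(idx))
    stop("n = ", n, " exceeds the ", length(idx), " masked pixels; ",
         "choose a smaller n (or enlarge the target window)")
  if (m < 1L) stop("m must be >= 1")
  chan <- if (channel == "real") Re(vals[idx]) else Im(vals[idx])
  withSeed(seed, lapply(seq_len(m), function(k) {
    picked <- chan[sample.int(length(idx), n, replace = FALSE)]
    samplingSegment(picked, channel = channel, sourceId = sourceId,
                    seed = seed)
  }))
}

#' Two-sample variance-ratio (F) test for equality of dispersions
#'
#' Tests \eqn{H_0: \sigma_r^2 = \sigma_s^2} against a two-sided alternative
#' with the statistic \eqn{F = \hat V[r] / \hat V[s]} (unbiased sample
#' variances), distributed as \eqn{F_{(n_r-1),(n_s-1)}} under the Gaussian
#' null. \eqn{H_0} is accepted iff \eqn{F} lies in the two-tailed acceptance
#' interval \eqn{[F_{\alpha/2}, F_{1-\alpha/2}]} (lower-tail quantiles). The
#' returned \eqn{1-\alpha} confidence interval for the population variance
#' ratio is \eqn{(F/F_{1-\alpha/2},\; F/F_{\alpha/2})}; it contains 1
#' exactly when \eqn{H_0} is accepted.
#'
#' The p-value is either analytic, \eqn{2\min\{P(F' \le F), P(F' \ge F)\}},
#' or an empirical Monte-Carlo estimate: `nMC` null ratios are simulated
#' from Gaussian samples with the pooled variance and compared to the
#' observed ratio on the \eqn{|\log F|} scale, with the add-one estimator
#' \eqn{(1 + \#\{\text{as extreme}\})/(1 + n_{MC})}.
#'
#' @param ref reference [SamplingSegment-class] (or numeric vector).
#' @param input input [SamplingSegment-class] (or numeric vector).
#' @param alpha significance level in (0, 1); default 0.01.
#' @param pMode `"analytic"` (default) or `"monte_carlo"`.
#' @param nMC number of Monte-Carlo null ratios (default 10000).
#' @param seed integer seed for the Monte-Carlo mode.
#' @return a [VarianceRatioResult-class].
#' @export
#' @examples
#' set.seed(1)
#' r <- varianceRatioTest(rnorm(200, 0, 2), rnorm(200, 0, 1), alpha = 0.01)
#' statValue(r); decision(r)
varianceRatioTest <- function(ref, input, alpha = 0.01,
                              pMode = c("analytic", "monte_carlo"),
                              nMC = 10000L, seed = 1L) {
  pMode <- match.arg(pMode)
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  checkSameChannel(ref, input)
  x <- segValues(ref); y <- segValues(input)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop("both segments need at least 2 values")
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (v1 == 0 || v2 == 0)
    stop("degenerate segment: zero sample variance")
  Fobs <- v1 / v2
  df1 <- n1 - 1; df2 <- n2 - 1
  lo <- stats::qf(alpha / 2, df1, df2)
  hi <- stats::qf(1 - alpha / 2, df1, df2)
  inside <- Fobs >= lo && Fobs <= hi
  if (pMode == "analytic") {
    p <- 2 * min(stats::pf(Fobs, df1, df2), stats::pf(Fobs, df1, df2,
                                                      lower.tail = FALSE))
    p <- min(p, 1)
  } else {
    sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
    p <- withSeed(seed, {
      a <- colVars(matrix(stats::rnorm(nMC * n1, 0, sp), n1, nMC))
      b <- colVars(matrix(stats::rnorm(nMC * n2, 0, sp), n2, nMC))
      (1 + sum(abs(log(a / b)) >= abs(log(Fobs)))) / (1 + nMC)
    })
  }
  new("VarianceRatioResult",
      statistic = Fobs, dof = c(df1, df2), variances = c(v1, v2),
      alpha = alpha, acceptInterval = c(lo, hi), pValue = p, pMode = pMode,
      decision = if (inside) "accept_H0" else "reject_H0",
      ciVarianceRatio = c(Fobs / hi, Fobs / lo))
}

#' Empirical cumulative distribution function on a grid
#'
#' Fraction of `values` less than or equal to each grid point
#' (right-continuous step function sampled on the grid).
#'
#' @param values nonempty numeric vector.
#' @param grid numeric vector of evaluation points, sorted ascending.
#' @return numeric vector in `[0, 1]`, one entry per grid point.
#' @export
#' @examples
#' ecdfEval(c(0, 1), c(0, 1, 2, 3))  # 0.5 1 1 1
ecdfEval <- function(values, grid) {
  values <- segValues(values)
  if (length(values) == 0L) stop("'values' must be nonempty")
  if (is.unsorted(grid)) stop("'grid' must be sorted ascending")
  stats::ecdf(values)(grid)
}

# evaluation grid shared by two segments
.ecdfGrid <- function(x, y, gridMode, gridN) {
  if (gridMode == "pooled_points") sort(unique(c(x, y)))
  else seq(min(x, y), max(x, y), length.out = gridN)
}

#' ECDF discriminant statistic between two sampling segments
#'
#' Mean squared difference between the two empirical CDFs over an evaluation
#' grid: \eqn{\Lambda = \mathrm{mean}_u [f_a(u) - f_b(u)]^2 \in [0, 1]}.
#' Computed between two reference draws it is the null statistic
#' \eqn{\tilde\Lambda}; between a reference and an unknown input it is the
#' observed \eqn{\Lambda}. With the default pooled-points grid the statistic
#' is invariant under monotone rescaling of the values and symmetric in its
#' arguments.
#'
#' @param a,b [SamplingSegment-class] objects or numeric vectors (same
#'   channel).
#' @param gridMode `"pooled_points"` (default; grid = sorted unique pooled
#'   sample values) or `"fixed_linear"`.
#' @param gridN grid size for `"fixed_linear"`.
#' @return the statistic, a number in `[0, 1]`.
#' @export
#' @examples
#' ecdfStatistic(c(0, 1), c(2, 3))  # 0.375
ecdfStatistic <- function(a, b, gridMode = c("pooled_points", "fixed_linear"),
                          gridN = 256L) {
  gridMode <- match.arg(gridMode)
  checkSameChannel(a, b)
  x <- segValues(a); y <- segValues(b)
  if (length(x) == 0L || length(y) == 0L) stop("segments must be nonempty")
  grid <- .ecdfGrid(x, y, gridMode, gridN)
  if (length(grid) == 0L) stop("empty evaluation grid")
  mean((ecdfEval(x, grid) - ecdfEval(y, grid))^2)
}

#' Null distribution of the ECDF statistic from reference segments
#'
#' Pairs up disjoint reference segments — (1,2), (3,4), ... — and returns
#' the \eqn{\tilde\Lambda} statistic of each pair: the Monte-Carlo null
#' ("criterion discriminant function") for [ecdfTest].
#'
#' @param refSegments list of at least 2 reference
#'   [SamplingSegment-class]s (or numeric vectors).
#' @inheritParams ecdfStatistic
#' @return numeric vector of `floor(length(refSegments)/2)` null values.
#' @export
ecdfNull <- function(refSegments, gridMode = c("pooled_points", "fixed_linear"),
                     gridN = 256L) {
  gridMode <- match.arg(gridMode)
  npair <- length(refSegments) %/% 2L
  if (npair < 1L) stop("need at least 2 reference segments")
  vapply(seq_len(npair), function(k)
    ecdfStatistic(refSegments[[2L * k - 1L]], refSegments[[2L * k]],
                  gridMode = gridMode, gridN = gridN),
    numeric(1))
}

#' Nonparametric ECDF discriminant test
#'
#' Distribution-free two-sample test for whether the input segment comes
#' from the same population as the reference image. The null distribution
#' is built from \eqn{\tilde\Lambda} statistics of disjoint reference-
#' segment pairs (`refSegments[-pivot]`); the observed statistic is
#' \eqn{\Lambda} between the pivot reference segment and the input. The
#' p-value is the add-one upper-tail proportion
#' \eqn{(1 + \#\{\tilde\Lambda \ge \Lambda\})/(1 + n_{null})} and \eqn{H_0}
#' is rejected iff \eqn{p < \alpha}.
#'
#' Note the granularity constraint: the smallest attainable p-value is
#' \eqn{1/(1 + n_{null})}, so rejection at \eqn{\alpha} requires
#' \eqn{n_{null} > 1/\alpha - 1} null pairs (e.g. > 99 pairs for
#' \eqn{\alpha = 0.01}). A precomputed null (e.g. from [ecdfNull]) can be
#' passed to avoid recomputation across trials against the same reference.
#'
#' @param refSegments list of reference segments (>= 2) used for the pivot
#'   and, unless `nullStatistics` is given, the null pairs.
#' @param input the input [SamplingSegment-class] (or numeric vector).
#' @param alpha significance level (default 0.01).
#' @param pivot index of the reference segment compared against the input
#'   (default 1).
#' @param nullStatistics optional precomputed \eqn{\tilde\Lambda} vector.
#' @inheritParams ecdfStatistic
#' @return an [EcdfTestResult-class].
#' @export
#' @examples
#' set.seed(2)
#' refs <- replicate(41, rnorm(50), simplify = FALSE)
#' res <- ecdfTest(refs, rnorm(50, 0, 3), alpha = 0.05)
#' decision(res)
ecdfTest <- function(refSegments, input, alpha = 0.01, pivot = 1L,
                     nullStatistics = NULL,
                     gridMode = c("pooled_points", "fixed_linear"),
                     gridN = 256L) {
  gridMode <- match.arg(gridMode)
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  if (is.null(nullStatistics)) {
    if (length(refSegments) < 2L) stop("need at least 2 reference segments")
    nullStatistics <- ecdfNull(refSegments[-pivot], gridMode = gridMode,
                               gridN = gridN)
  }
  lambda <- ecdfStatistic(refSegments[[pivot]], input, gridMode = gridMode,
                          gridN = gridN)
  p <- (1 + sum(nullStatistics >= lambda)) / (1 + length(nullStatistics))
  new("EcdfTestResult", statistic = lambda, nullStatistics = nullStatistics,
      pValue = p, alpha = alpha,
      decision = if (p < alpha) "reject_H0" else "accept_H0")
}
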