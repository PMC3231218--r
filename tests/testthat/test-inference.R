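test_that("segment drawing is exhaustive, reproducible and validated", {
  cfg <- testOptics(64L)
  fld <- randomComplexField(cfg, seed = 2)
  mask <- matrix(FALSE, 64, 64)
  mask[20:40, 15:45] <- TRUE

  # exhaustive draw is a permutation of all masked values
  all_vals <- Re(fieldValues(fld)[mask])
  seg <- drawSegments(fld, mask, n = sum(mask), m = 1, channel = "real",
                      seed = 4)[[1]]
  expect_equal(sort(segmentValues(seg)), sort(all_vals))

  # requested shape: m segments of n values each
  segs <- drawSegments(fld, mask, n = 200, m = 100, channel = "imaginary",
                       seed = 4)
  expect_length(segs, 100)
  expect_true(all(vapply(segs, function(s) s@n, integer(1)) == 200L))
  expect_true(all(vapply(segs, function(s) s@channel, "") == "imaginary"))

  # seeded reproducibility, and sensitivity to the seed
  again <- drawSegments(fld, mask, n = 200, m = 100, channel = "imaginary",
                        seed = 4)
  expect_identical(lapply(segs, segmentValues), lapply(again, segmentValues))
  other <- drawSegments(fld, mask, n = 200, m = 100, channel = "imaginary",
                        seed = 5)
  expect_false(identical(segmentValues(segs[[1]]), segmentValues(other[[1]])))

  # within a segment pixels are distinct sites (distinct values here since
  # the random field has no repeated values)
  expect_identical(anyDuplicated(segmentValues(segs[[1]])), 0L)

  expect_error(drawSegments(fld, mask, n = sum(mask) + 1, m = 1,
                            channel = "real"), "smaller n")
})

test_that("variance-ratio test matches F-distribution theory", {
  # identical segments: F = 1, accepted at any alpha
  x <- rnorm(50)
  r0 <- varianceRatioTest(x, x, alpha = 0.2)
  expect_equal(statValue(r0), 1)
  expect_equal(decision(r0), "accept_H0")

  # known variance ratio 4 at n = 200: estimate near 4, rejected at 0.01
  set.seed(42)
  a <- rnorm(200, 0, 2); b <- rnorm(200, 0, 1)
  r <- varianceRatioTest(a, b, alpha = 0.01)
  expect_equal(statValue(r), 4, tolerance = 0.35)
  expect_equal(decision(r), "reject_H0")
  expect_equal(statValue(r), stats::var(a) / stats::var(b))

  # analytic p against a numerically integrated F density (oracle)
  dens <- function(f) stats::df(f, 199, 199)
  lower <- stats::integrate(dens, 0, statValue(r), rel.tol = 1e-10)$value
  pOracle <- 2 * min(lower, 1 - lower)
  expect_equal(pValue(r), pOracle, tolerance = 1e-6)

  # Eq.-8-style confidence interval is consistent with the decision
  expect_true(r@ciVarianceRatio[1] > 1 || r@ciVarianceRatio[2] < 1)
  racc <- varianceRatioTest(rnorm(100), rnorm(100), alpha = 0.05, seed = 9)
  if (decision(racc) == "accept_H0")
    expect_true(racc@ciVarianceRatio[1] < 1 && racc@ciVarianceRatio[2] > 1)

  expect_error(varianceRatioTest(rep(1, 10), rnorm(10)), "degenerate")
  expect_error(varianceRatioTest(rnorm(10), rnorm(10), alpha = 1.2), "alpha")
})

test_that("Monte-Carlo and analytic p-values agree", {
  set.seed(7)
  a <- rnorm(200, 0, 1.1); b <- rnorm(200, 0, 1)
  pa <- pValue(varianceRatioTest(a, b, pMode = "analytic"))
  pm <- pValue(varianceRatioTest(a, b, pMode = "monte_carlo",
                                 nMC = 10000L, seed = 11))
  expect_lt(abs(pa - pm), 3 / sqrt(10000))
})

test_that("F-test power grows with the variance ratio", {
  nrep <- 300
  rates <- vapply(c(1, 2, 4), function(ratio) {
    set.seed(100 + ratio)
    rej <- vapply(seq_len(nrep), function(i) {
      decision(varianceRatioTest(rnorm(200, 0, sqrt(ratio)),
                                 rnorm(200), alpha = 0.01)) == "reject_H0"
    }, logical(1))
    mean(rej)
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[3], 0.99)
})

test_that("the ECDF and its discriminant statistic match hand computation", {
  expect_equal(ecdfEval(c(0, 1), c(0, 1, 2, 3)), c(0.5, 1, 1, 1))
  # range limits
  set.seed(3)
  v <- rnorm(25)
  expect_equal(ecdfEval(v, min(v) - 1), 0)
  expect_equal(ecdfEval(v, max(v) + 1), 1)
  # brute-force counting oracle
  g <- sort(runif(40, -3, 3))
  expect_equal(ecdfEval(v, g),
               vapply(g, function(u) sum(v <= u) / length(v), numeric(1)))
  expect_error(ecdfEval(numeric(0), 0:1), "nonempty")
  expect_error(ecdfEval(v, c(1, 0)), "sorted")

  # hand-computable pooled-grid statistic
  expect_equal(ecdfStatistic(c(0, 1), c(2, 3)), 0.375)
  expect_equal(ecdfStatistic(v, v), 0)

  # symmetry and the [0, 1] range bound over random pairs
  set.seed(9)
  for (i in 1:250) {
    a <- rnorm(30, sd = runif(1, 0.5, 3))
    b <- rnorm(30, mean = runif(1, -2, 2))
    lam <- ecdfStatistic(a, b)
    expect_true(lam >= 0 && lam <= 1)
    expect_equal(lam, ecdfStatistic(b, a))
  }

  # channel mismatch is refused
  expect_error(ecdfStatistic(samplingSegment(v, "real"),
                             samplingSegment(v, "imaginary")), "channels")
})

test_that("the ECDF discriminant test is calibrated and consistent", {
  # identical pivot and input: Lambda = 0, add-one p = 1
  set.seed(21)
  refs <- replicate(11, rnorm(40), simplify = FALSE)
  r0 <- ecdfTest(refs, refs[[1]], alpha = 0.05)
  expect_equal(statValue(r0), 0)
  expect_equal(pValue(r0), 1)
  expect_true(all(nullStats(r0) >= 0))

  # p-value attains only values in [1/(1+n_null), 1]
  expect_gte(pValue(r0), 1 / (1 + length(nullStats(r0))))

  # extreme separation: 5 pooled-sd shift is always rejected
  set.seed(22)
  refs200 <- replicate(201, rnorm(200), simplify = FALSE)
  shifted <- rnorm(200, mean = 5)
  expect_equal(decision(ecdfTest(refs200, shifted, alpha = 0.01)),
               "reject_H0")

  expect_error(ecdfTest(refs200[1], rnorm(200)), "at least 2")
})

test_that("ECDF test null rejection rate matches its nominal level", {
  # under H0 the add-one p is discrete-uniform on {1/101, ..., 1}, so with
  # 100 null pairs the strict p < 0.01 rule rejects only at p = 1/101:
  # expected rate 1/101
  nrep <- 1000
  set.seed(31)
  rej <- vapply(seq_len(nrep), function(i) {
    refs <- replicate(201, rnorm(30), simplify = FALSE)
    decision(ecdfTest(refs, rnorm(30), alpha = 0.01)) == "reject_H0"
  }, logical(1))
  band <- stats::qbinom(c(0.005, 0.995), nrep, 1 / 101) / nrep
  expect_gte(mean(rej), band[1])
  expect_lte(mean(rej), band[2])
})
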