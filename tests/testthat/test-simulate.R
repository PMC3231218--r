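test_that("specimen generation honours dispersion, determinism and geometry", {
  cfg <- testOptics()

  # degenerate dispersion: constant phase on the support
  obj0 <- simulateSpecimen("filament", cfg, phaseDispersion = 0,
                           shapeParams = testShape("filament"), seed = 5)
  expect_equal(length(unique(phaseMap(obj0)[support(obj0)])), 1L)
  expect_equal(unique(phaseMap(obj0)[support(obj0)]), 1.0)
  ell0 <- simulateSpecimen("ellipse", cfg, phaseDispersion = 0,
                           shapeParams = list(semiMajor = 8e-6,
                                              semiMinor = 5e-6,
                                              patternDepth = 0), seed = 5)
  expect_equal(length(unique(phaseMap(ell0)[support(ell0)])), 1L)

  # determinism: same seed -> identical object; phase zero off support
  a <- simulateSpecimen("filament", cfg, phaseDispersion = 0.4,
                        shapeParams = testShape("filament"), seed = 11)
  b <- simulateSpecimen("filament", cfg, phaseDispersion = 0.4,
                        shapeParams = testShape("filament"), seed = 11)
  expect_identical(phaseMap(a), phaseMap(b))
  expect_identical(support(a), support(b))
  expect_true(all(phaseMap(a)[!support(a)] == 0))
  d <- simulateSpecimen("filament", cfg, phaseDispersion = 0.4,
                        shapeParams = testShape("filament"), seed = 12)
  expect_false(identical(support(a), support(d)))

  # ribbon support area vs closed-form length x width / pitch^2 (+-10%)
  for (s in 1:5) {
    obj <- simulateSpecimen("filament", cfg, phaseDispersion = 0.3,
                            shapeParams = testShape("filament"), seed = s)
    analytic <- 40e-6 * 5e-6 / prod(cfg@pixelPitch)
    expect_lt(abs(sum(support(obj)) - analytic) / analytic, 0.10)
  }

  # unknown class names the registered classes
  expect_error(simulateSpecimen("amoeba", cfg), "filament, ellipse")
  # support that cannot be drawn on the grid
  expect_error(simulateSpecimen("ellipse", cfg,
    shapeParams = list(semiMajor = 1e-9, semiMinor = 1e-9)), "empty")
})

test_that("Fresnel propagation conserves power, inverts and composes", {
  cfg <- testOptics(64L)
  f0 <- randomComplexField(cfg, seed = 3)
  p0 <- sum(Mod(fieldValues(f0))^2)

  # identity at zero distance
  expect_identical(fieldValues(forwardPropagate(f0, 0)), fieldValues(f0))

  for (d in c(25e-6, -10e-6, 1e-3)) {
    f1 <- forwardPropagate(f0, d)
    expect_lt(abs(sum(Mod(fieldValues(f1))^2) / p0 - 1), 1e-9)
    # inverse pair
    f2 <- forwardPropagate(f1, -d)
    expect_lt(max(Mod(fieldValues(f2) - fieldValues(f0))) /
                max(Mod(fieldValues(f0))), 1e-8)
  }

  # group property: d1 then d2 equals d1 + d2
  g12 <- forwardPropagate(forwardPropagate(f0, 10e-6), 15e-6)
  g3 <- forwardPropagate(f0, 25e-6)
  expect_lt(relRMS(fieldValues(g12), fieldValues(g3)), 1e-8)

  # dimension mismatch
  expect_error(forwardPropagate(matrix(0 + 0i, 32, 32), 1e-6, optics = cfg),
               "dimensions")
})

test_that("frequency-domain propagation matches the brute-force Fresnel oracle", {
  cfg <- testOptics(64L)
  # discrete point scatterer
  pt <- matrix(0 + 0i, 64, 64); pt[33, 33] <- 1 + 0i
  got <- fieldValues(forwardPropagate(pt, 25e-6, optics = cfg))
  want <- oraclePropagate(pt, 25e-6, cfg)
  expect_lt(relRMS(got, want), 1e-6)
  # and for a generic random field
  f0 <- randomComplexField(cfg, seed = 9)
  got <- fieldValues(forwardPropagate(f0, 25e-6))
  want <- oraclePropagate(fieldValues(f0), 25e-6, cfg)
  expect_lt(relRMS(got, want), 1e-6)
})

test_that("hologram recording follows the interference model", {
  cfg <- testOptics(128L)

  # no object: intensity constant A_r^2 with zero variance
  blank <- new("PhaseObject",
               phaseMap = matrix(0, 128, 128),
               support = {
                 s <- matrix(FALSE, 128, 128); s[64, 64] <- TRUE; s
               },
               axialExtent = 0, classLabel = "filament", optics = cfg)
  h0 <- recordHologram(blank, refAmplitude = 1.5)
  expect_lt(max(abs(holoIntensity(h0) - 1.5^2)), 1e-12)
  expect_lt(stats::var(as.vector(holoIntensity(h0))), 1e-24)
  expect_true(all(holoIntensity(h0) >= 0))

  obj <- simulateSpecimen("ellipse", cfg, phaseDispersion = 0.5,
    shapeParams = list(semiMajor = 6e-6, semiMinor = 4e-6), seed = 4)

  # deterministic when noise-free
  expect_identical(holoIntensity(recordHologram(obj)),
                   holoIntensity(recordHologram(obj)))

  # algebraic expansion: I - A_r^2 = |O_h|^2 + 2 A_h A_r cos(phi_h - phi_r)
  Ar <- 1.2; phir <- 0.3
  h <- recordHologram(obj, refAmplitude = Ar, refPhase = phir)
  oh <- fieldValues(forwardPropagate(exp(1i * phaseMap(obj)) - 1,
                                     cfg@distance, optics = cfg))
  expanded <- Mod(oh)^2 + 2 * Mod(oh) * Ar * cos(Arg(oh) - phir)
  expect_lt(max(abs((holoIntensity(h) - Ar^2) - expanded)), 1e-12)
  expect_equal(mean(holoIntensity(h)) - Ar^2, mean(expanded), tolerance = 1e-12)

  # noise is seeded and clipped at zero
  hn1 <- recordHologram(obj, noiseSigma = 0.5, seed = 3)
  hn2 <- recordHologram(obj, noiseSigma = 0.5, seed = 3)
  expect_identical(holoIntensity(hn1), holoIntensity(hn2))
  expect_true(all(holoIntensity(hn1) >= 0))
  expect_error(recordHologram(obj, refAmplitude = 0), "positive")
})
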