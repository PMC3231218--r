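test_that("reconstruction handles constant holograms and is linear", {
  cfg <- testOptics(64L)

  # constant hologram, mean subtracted -> identically zero field
  h <- matrix(2.5, 64, 64)
  z <- reconstructField(h, optics = cfg, dcSuppression = "subtract_mean")
  expect_true(all(Mod(fieldValues(z)) < 1e-14))

  # uniform input is a propagation eigenfunction: uniform modulus out
  u <- reconstructField(h, optics = cfg, dcSuppression = "none")
  expect_lt(diff(range(Mod(fieldValues(u)))), 1e-12)
  expect_equal(mean(Mod(fieldValues(u))), 2.5, tolerance = 1e-12)

  # linearity without DC suppression
  set.seed(8)
  i1 <- matrix(runif(64^2), 64, 64)
  i2 <- matrix(runif(64^2), 64, 64)
  lhs <- fieldValues(reconstructField(2 * i1 + 3 * i2, optics = cfg,
                                      dcSuppression = "none"))
  rhs <- 2 * fieldValues(reconstructField(i1, optics = cfg,
                                          dcSuppression = "none")) +
         3 * fieldValues(reconstructField(i2, optics = cfg,
                                          dcSuppression = "none"))
  expect_lt(relRMS(lhs, rhs), 1e-10)

  expect_error(reconstructField(matrix(NaN, 64, 64), optics = cfg),
               "non-finite")
})

test_that("reconstruction focuses at the recording distance", {
  rec <- testReconstruction("filament", seed = 2)
  obj <- rec$object
  holo <- recordHologram(obj)
  sup <- support(obj)
  trueMod <- Mod(exp(1i * phaseMap(obj)) - 1)[sup]

  ncc <- function(d0) {
    f <- reconstructField(holo, distance = d0)
    stats::cor(Mod(fieldValues(f))[sup], trueMod)
  }
  offsets <- c(-10e-6, -6e-6, -3e-6, 0, 3e-6, 6e-6, 10e-6)
  scores <- vapply(25e-6 + offsets, ncc, numeric(1))
  expect_equal(which.max(scores), which(offsets == 0))

  # blind sharpness (energy concentration, inverse participation ratio of
  # the intensity) is maximal in focus for a strongly dispersive specimen.
  # (A nearly uniform phase screen scatters little amplitude contrast at
  # perfect focus, so blind contrast metrics peak slightly defocused for
  # weakly dispersive objects — the truth-based NCC above covers that case.)
  rec2 <- testReconstruction("ellipse", seed = 2, phaseDispersion = 0.9)
  holo2 <- recordHologram(rec2$object)
  concentration <- function(d0) {
    p <- Mod(fieldValues(reconstructField(holo2, distance = d0)))^2
    sum(p^2) / sum(p)^2
  }
  sharp <- vapply(25e-6 + offsets, concentration, numeric(1))
  expect_equal(which.max(sharp), which(offsets == 0))
})

test_that("reconstructed energy concentrates on the specimen support", {
  # sign test over 20 simulated specimens: power fraction inside the
  # 2-px-dilated support beats a random mask of equal area
  wins <- 0L
  for (s in 1:20) {
    class <- if (s %% 2 == 0) "filament" else "ellipse"
    rec <- testReconstruction(class, seed = s, dims = 128L)
    pw <- Mod(fieldValues(rec$field))^2
    dil <- dilateBy(support(rec$object), 2L)
    inFrac <- sum(pw[dil]) / sum(pw)
    set.seed(1000 + s)
    rnd <- matrix(FALSE, 128, 128)
    rnd[sample.int(128^2, sum(dil))] <- TRUE
    rndFrac <- sum(pw[rnd]) / sum(pw)
    wins <- wins + (inFrac > rndFrac)
  }
  expect_lt(stats::binom.test(wins, 20, 0.5,
                              alternative = "greater")$p.value, 0.01)
})

test_that("padding changes edge behaviour only mildly on centred objects", {
  rec <- testReconstruction("ellipse", seed = 6, phaseDispersion = 0.9)
  holo <- recordHologram(rec$object)
  plain <- reconstructField(holo)
  padded <- reconstructField(holo, pad = TRUE)
  sup <- support(rec$object)
  # with the fringe field well inside the frame, wrap-around is negligible
  # and the two reconstructions agree on the support
  expect_gt(stats::cor(Mod(fieldValues(padded)[sup]),
                       Mod(fieldValues(plain)[sup])), 0.99)
  expect_lt(relRMS(fieldValues(padded)[sup], fieldValues(plain)[sup]), 0.05)
})
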