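test_that("noiseless trace reproduces the configured kinematics", {
  p <- BreathingParams(30, 10, 0.25, noiseSd = 0)
  tr <- simulateBreathingTrace(p, 60, 30)
  expect_equal(max(siValues(tr)) - min(siValues(tr)), 30)
  expect_equal(max(apValues(tr)) - min(apValues(tr)), 10)
  expect_equal(dominantFrequency(siValues(tr), 30), 0.25)
  # also under the sinusoid waveform
  trs <- simulateBreathingTrace(BreathingParams(30, 10, 0.25,
                                                waveform = "sinusoid",
                                                noiseSd = 0), 60, 30)
  expect_equal(max(siValues(trs)) - min(siValues(trs)), 30)
  expect_equal(dominantFrequency(siValues(trs), 30), 0.25)
})

test_that("zero-amplitude parameters give a constant-zero trace", {
  tr <- simulateBreathingTrace(BreathingParams(0, 0, 0.25, noiseSd = 0), 20, 10)
  expect_true(all(siValues(tr) == 0))
  expect_true(all(apValues(tr) == 0))
})

test_that("trace generation rejects degenerate arguments and is seeded", {
  p <- BreathingParams(noiseSd = 1, seed = 42L)
  expect_error(simulateBreathingTrace(p, -1, 30), "positive")
  expect_error(simulateBreathingTrace(p, 60, 0), "positive")
  a <- simulateBreathingTrace(p, 10, 30)
  b <- simulateBreathingTrace(p, 10, 30)
  expect_identical(siValues(a), siValues(b))
  c <- simulateBreathingTrace(BreathingParams(noiseSd = 1, seed = 43L), 10, 30)
  expect_false(identical(siValues(a), siValues(c)))
})

test_that("surface sequence elevates the rest patch by coupling * AP", {
  patch <- SurfacePatchModel(extent = 0.02, spacing = 0.001, bumpHeight = 0,
                             coupling = 1, depthNoiseSd = 0)
  # constant AP of 5 mm: every point sits exactly 5 mm above rest
  tr <- DisplacementTrace(c(0, 1), si = c(0, 0), ap = c(5, 5))
  seq1 <- simulateSurfaceSequence(tr, patch, rate = 2)
  rest <- simulateSurfaceSequence(DisplacementTrace(c(0, 1), c(0, 0), c(0, 0)),
                                  patch, rate = 2)
  dz <- cloudPoints(seq1[[1]])[, 3] - cloudPoints(rest[[1]])[, 3]
  expect_equal(dz, rep(0.005, length(dz)))
  # zero AP: all frames identical to rest
  expect_identical(cloudPoints(rest[[1]]), cloudPoints(rest[[2]]))
  # constant point count and 1/rate timestamps
  expect_equal(nPoints(seq1[[1]]), nPoints(seq1[[2]]))
  expect_equal(timestamps(seq1[[2]]) - timestamps(seq1[[1]]), 0.5)
})

test_that("elevated flat grid has nearest-rest-point distance = elevation", {
  # 1 mm grid spacing, 5 mm elevation: the vertical neighbor (5) beats the
  # lateral one (sqrt(26)) for interior points
  rest <- flatGrid(spacingMm = 1, halfSpanMm = 5, heightMm = 0)
  up <- flatGrid(spacingMm = 1, halfSpanMm = 5, heightMm = 5)
  d <- vapply(seq_len(nrow(up)), function(i)
    min(sqrt(colSums((t(rest) - up[i, ])^2))), numeric(1))
  expect_equal(d, rep(0.005, nrow(up)))
})

test_that("session set applies per-session scales, shifts and holds", {
  proto <- ProtocolSpec(sessionDuration = 60, nSessions = 3L,
                        breathholdDuration = 5, surrogateRate = 30,
                        groundtruthRate = 15)
  p <- BreathingParams(30, 10, 0.25, noiseSd = 0, seed = 7L)
  vars <- list(SessionVariability(1.0), SessionVariability(0.9),
               SessionVariability(1.1, baselineShift = 2))
  set <- simulateSessionSet(p, proto, vars, clouds = FALSE)
  p2t <- vapply(set, function(s)
    max(siValues(s$trace)) - min(siValues(s$trace)), numeric(1))
  expect_equal(p2t, c(30, 27, 33))
  # baseline shift moves the whole SI channel
  expect_equal(min(siValues(set[[3]]$trace)), 2)
  # flat zero-variance breath-holds in the first and last 5 s
  for (s in set) {
    tt <- timestamps(s$trace)
    expect_equal(stats::var(siValues(s$trace)[tt < 5]), 0)
    expect_equal(stats::var(siValues(s$trace)[tt > 55]), 0)
  }
  expect_error(simulateSessionSet(p, proto, vars[1:2]), "one SessionVariability")
})

test_that("identical variability gives statistically identical sessions", {
  proto <- ProtocolSpec(sessionDuration = 20, breathholdDuration = 2)
  p <- BreathingParams(30, 10, 0.25, noiseSd = 0, seed = 3L)
  vars <- replicate(3, SessionVariability(), simplify = FALSE)
  set <- simulateSessionSet(p, proto, vars, clouds = FALSE)
  # noiseless and jitter-free: traces coincide exactly
  expect_equal(siValues(set[[1]]$trace), siValues(set[[2]]$trace))
  expect_equal(siValues(set[[2]]$trace), siValues(set[[3]]$trace))
})

test_that("fixed master seed regenerates the dataset bit-identically", {
  proto <- ProtocolSpec(sessionDuration = 12, breathholdDuration = 2)
  p <- BreathingParams(noiseSd = 0.5, seed = 11L)
  patch <- SurfacePatchModel(extent = 0.04, spacing = 0.01)
  vars <- replicate(3, SessionVariability(frequencyJitter = 0.05),
                    simplify = FALSE)
  a <- simulateSessionSet(p, proto, vars, patch = patch)
  b <- simulateSessionSet(p, proto, vars, patch = patch)
  expect_identical(siValues(a[[2]]$trace), siValues(b[[2]]$trace))
  expect_identical(cloudPoints(a[[3]]$clouds[[5]]),
                   cloudPoints(b[[3]]$clouds[[5]]))
})

test_that("mask edge follows SI displacement in pixel units", {
  # a 0.27 cm SI step at 0.027 cm/px moves the edge exactly 10 columns
  tr <- DisplacementTrace(c(0, 1), si = c(0, 2.7))
  masks <- simulateMaskSequence(tr, imageSize = c(64, 96), restColumn = 40,
                                rowBand = c(16, 48))
  rightCol <- vapply(masks, function(m) max(which(maskMatrix(m) == 1L,
                                                  arr.ind = TRUE)[, 2]) - 1L,
                     integer(1))
  expect_equal(rightCol, c(40L, 50L))
  # constant trace: identical masks
  masks0 <- simulateMaskSequence(DisplacementTrace(c(0, 1), c(0, 0)),
                                 imageSize = c(64, 96), restColumn = 40,
                                 rowBand = c(16, 48))
  expect_identical(maskMatrix(masks0[[1]]), maskMatrix(masks0[[2]]))
  # excursion overflowing the image is rejected
  expect_error(simulateMaskSequence(DisplacementTrace(c(0, 1), c(0, 500)),
                                    imageSize = c(64, 96)), "fit inside")
})

test_that("sinusoidal mask sequence spans the expected column excursion", {
  p <- BreathingParams(30, 10, 0.25, noiseSd = 0)
  tr <- simulateBreathingTrace(p, 20, 15)
  masks <- simulateMaskSequence(tr, imageSize = c(96, 160),
                                pixelSpacing = 0.027, rowBand = c(24, 72))
  rightCol <- vapply(masks, function(m) max(which(maskMatrix(m) == 1L,
                                                  arr.ind = TRUE)[, 2]),
                     integer(1))
  # 3.0 cm / 0.027 cm/px ~ 111 columns, up to rounding
  expect_equal(max(rightCol) - min(rightCol), 111, tolerance = 0.01)
  # masks are single 8-connected components
  lab <- rimest:::.cpp_label8(maskMatrix(masks[[1]]))
  expect_equal(max(lab), 1L)
})
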