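test_that("contrast stretch normalizes to [0, 1] and handles constant frames", {
  set.seed(21)
  img <- matrix(runif(600 * 700, 10, 200), 600, 700)
  out <- preprocessImage(img, RoiBox(0, 512, 100, 612))
  expect_equal(dim(out), c(512L, 512L))
  expect_gte(min(out), 0)
  expect_lte(max(out), 1)
  expect_gt(max(out) - min(out), 0.99)
  flat <- preprocessImage(matrix(7, 20, 20), RoiBox(0, 10, 0, 10))
  expect_true(all(flat == 0))
  expect_error(preprocessImage(img, RoiBox(0, 700, 0, 512)), "outside")
})

test_that("post-processing keeps the largest component and fills holes", {
  m <- matrix(0L, 12, 12)
  m[2:4, 2:5] <- 1L          # 12-pixel component
  m[8:9, 9] <- 1L            # 2-pixel component, dropped
  out <- postprocessMask(m, closingRadius = 0)
  expect_equal(sum(out), 12L)
  expect_equal(sum(out[8:9, 9]), 0L)
  # interior hole is filled
  h <- solidMask(10, 10, 2, 8, 2, 8)
  h[5, 5] <- 0L
  expect_equal(postprocessMask(h, closingRadius = 0), solidMask(10, 10, 2, 8, 2, 8))
  # idempotent on an already-clean component
  clean <- solidMask(10, 10, 1, 6, 1, 7)
  expect_equal(postprocessMask(clean, closingRadius = 0), clean)
  expect_error(postprocessMask(matrix(0L, 5, 5), frame = 3L), "frame 3")
  # diagonal pixels belong to one 8-connected component
  d <- matrix(0L, 5, 5)
  d[cbind(1:3, 1:3)] <- 1L
  d[5, 5] <- 1L
  expect_equal(sum(postprocessMask(d, closingRadius = 0)), 3L)
})

test_that("edge extraction follows the 4-neighbor boundary definition", {
  sq <- solidMask(5, 5, 1, 4, 1, 4)   # 3x3 solid square
  e <- extractEdge(sq)
  expect_equal(nrow(e), 8L)           # all but the center pixel
  expect_false(any(e[, "row"] == 2 & e[, "col"] == 2))
  single <- matrix(0L, 3, 3); single[2, 2] <- 1L
  expect_equal(unname(extractEdge(single)), matrix(c(1L, 1L), 1))
  line <- matrix(0L, 5, 5); line[3, ] <- 1L
  expect_equal(nrow(extractEdge(line)), 5L)
  # a pixel on the image border is edge (border counts as background)
  full <- matrix(1L, 4, 4)
  expect_equal(nrow(extractEdge(full)), 12L)
})

test_that("Dice matches hand-enumerated overlaps and is symmetric", {
  a <- solidMask(6, 6, 1, 3, 1, 3)
  b <- solidMask(6, 6, 2, 4, 2, 4)   # 2x2 blocks overlapping in 1 px
  expect_equal(dice(a, b), 100 * 2 * 1 / 8)
  expect_equal(dice(a, b), dice(b, a))
  expect_equal(dice(a, a), 100)
  disj <- solidMask(6, 6, 4, 6, 4, 6)
  expect_equal(dice(a, disj), 0)
  expect_warning(d0 <- dice(matrix(0L, 3, 3), matrix(0L, 3, 3)), "undefined")
  expect_true(is.na(d0))
  expect_error(dice(a, matrix(0L, 3, 3)), "same shape")
})

test_that("Hausdorff distance matches brute force on toy sets", {
  h <- hausdorff(cbind(row = 0L, col = 0L), cbind(row = 3L, col = 4L))
  expect_equal(as.numeric(h), 5 * 0.027 * 10)   # 5 px = 1.35 mm
  expect_equal(attr(h, "px"), 5)
  # identical sets
  e <- extractEdge(solidMask(8, 8, 2, 6, 2, 6))
  expect_equal(as.numeric(hausdorff(e, e)), 0)
  # square edge shifted one column: 1 px
  e2 <- e; e2[, "col"] <- e2[, "col"] + 1L
  expect_equal(attr(hausdorff(e, e2), "px"), 1)
  # symmetry and triangle inequality on random point sets
  set.seed(31)
  ps <- replicate(3, cbind(row = sample.int(30, 8), col = sample.int(30, 8)),
                  simplify = FALSE)
  ab <- attr(hausdorff(ps[[1]], ps[[2]]), "px")
  ba <- attr(hausdorff(ps[[2]], ps[[1]]), "px")
  bc <- attr(hausdorff(ps[[2]], ps[[3]]), "px")
  ac <- attr(hausdorff(ps[[1]], ps[[3]]), "px")
  expect_equal(ab, ba)
  expect_lte(ac, ab + bc + 1e-12)
  # ROI restriction errors name the offending set
  roi <- RoiBox(0, 2, 0, 2)
  expect_error(hausdorff(cbind(row = 5L, col = 5L), cbind(row = 1L, col = 1L),
                         roi = roi), "first")
})

test_that("edge tracking converts pixel motion to displacement", {
  roi <- RoiBox(12, 48, 20, 96)
  # constant edge: all-zero trace
  tr0 <- DisplacementTrace(c(0, 1, 2), c(0, 0, 0))
  masks0 <- simulateMaskSequence(tr0, imageSize = c(64, 96), restColumn = 50,
                                 rowBand = c(10, 50))
  out0 <- trackDisplacement(masks0, roi, filter = FALSE, rate = 1)
  expect_equal(siValues(out0), c(0, 0, 0))
  # a 10-column step at 0.027 cm/px is 2.7 mm
  trs <- DisplacementTrace(c(0, 1), c(0, 2.7))
  masks <- simulateMaskSequence(trs, imageSize = c(64, 96), restColumn = 50,
                                rowBand = c(10, 50))
  out <- trackDisplacement(masks, roi, filter = FALSE, rate = 1)
  expect_equal(siValues(out), c(0, 2.7))
})

test_that("mask round trip recovers a sinusoid within one pixel", {
  p <- BreathingParams(30, 10, 0.25, noiseSd = 0)
  tr <- simulateBreathingTrace(p, 20, 15)
  masks <- simulateMaskSequence(tr, imageSize = c(96, 160),
                                pixelSpacing = 0.027, rowBand = c(24, 72))
  roi <- RoiBox(30, 66, 12, 160)
  rec <- trackDisplacement(masks, roi, filter = FALSE)
  err <- abs((siValues(rec) - siValues(rec)[1]) - (siValues(tr) - siValues(tr)[1]))
  expect_lte(max(err), 1 * 0.027 * 10)  # 1 px in mm
})

test_that("tracking-gap frames error out unless interpolation is allowed", {
  masks <- replicate(5, solidMask(20, 20, 5, 15, 2, 10), simplify = FALSE)
  roi <- RoiBox(0, 20, 0, 20)
  gappy <- masks
  gappy[[3]] <- matrix(0L, 20, 20)
  gappy[[3]][1, 15] <- 1L  # edge outside a narrow ROI
  roiN <- RoiBox(3, 18, 0, 12)
  expect_error(trackDisplacement(gappy, roiN, filter = FALSE, rate = 1),
               "frame 3")
  out <- trackDisplacement(gappy, roiN, filter = FALSE, rate = 1, maxGap = 1L)
  expect_equal(length(siValues(out)), 5L)
  expect_equal(siValues(out), rep(0, 5))  # interpolated over the gap
})

test_that("zero-phase filtering never amplifies a noisy trace", {
  set.seed(55)
  tt <- (0:599) / 15
  clean <- 15 * sin(2 * pi * 0.25 * tt)
  for (rep in 1:5) {
    noisy <- clean + rnorm(600, 0, 1)
    filt <- signal::filtfilt(signal::butter(2, 1 / (15 / 2), "low"), noisy)
    expect_lte(stats::var(filt - clean), stats::var(noisy - clean))
  }
  # and through the tracking interface: the low-pass never inflates the
  # variance of the tracked trace (it removes quantization chatter)
  p <- BreathingParams(30, 10, 0.25, noiseSd = 0)
  tr <- simulateBreathingTrace(p, 20, 15)
  masks <- simulateMaskSequence(tr, imageSize = c(96, 160), rowBand = c(24, 72))
  roi <- RoiBox(30, 66, 12, 160)
  raw <- trackDisplacement(masks, roi, filter = FALSE)
  fil <- trackDisplacement(masks, roi, filter = TRUE)
  # compare away from the forward-backward filter's boundary transients
  core <- timestamps(tr) > 2 & timestamps(tr) < 18
  expect_lte(stats::var(siValues(fil)[core]),
             stats::var(siValues(raw)[core]) * 1.001)
})

test_that("segmentation evaluation samples frames and aggregates Table-style metrics", {
  masks <- replicate(30, solidMask(24, 24, 4, 16, 4, 18), simplify = FALSE)
  ev <- evaluateSegmentation(masks, masks, nSamples = 20, seed = 2)
  expect_equal(length(ev$frames), 20L)
  s <- ev$summary
  expect_equal(s$mean[s$metric == "dice_pct"], 100)
  expect_equal(s$sd[s$metric == "dice_pct"], 0)
  expect_equal(s$mean[s$metric == "hausdorff_mm"], 0)
  # dilated prediction: Hausdorff exactly 1 px, Dice from area counts
  dil <- replicate(30, solidMask(24, 24, 3, 17, 3, 19), simplify = FALSE)
  ev2 <- suppressWarnings(evaluateSegmentation(dil, masks, nSamples = 40, seed = 2))
  expect_equal(length(ev2$frames), 30L)  # fewer frames than requested
  expect_true(length(ev2$warnings) > 0)
  s2 <- ev2$summary
  expect_equal(s2$mean[s2$metric == "hausdorff_px"], sqrt(2))
  areaA <- 14 * 16; areaB <- 12 * 14
  expect_equal(s2$mean[s2$metric == "dice_pct"], 100 * 2 * areaB / (areaA + areaB))
  # seeded sampling is reproducible
  ev3 <- evaluateSegmentation(masks, masks, nSamples = 20, seed = 2)
  expect_identical(ev$frames, ev3$frames)
})

test_that("per-cycle amplitude summary matches constructed breathing", {
  p <- BreathingParams(30, 10, 0.25, waveform = "sinusoid", noiseSd = 0)
  tr <- simulateBreathingTrace(p, 60, 30)
  s <- summarizeDisplacement(tr)
  expect_equal(s$mean, 30, tolerance = 1e-6)
  expect_equal(s$sd, 0, tolerance = 1e-6)
  expect_error(summarizeDisplacement(DisplacementTrace(0:9, rep(1, 10))),
               "constant")
  # alternating 40/20 mm cycles
  v <- c(0, 40, 0, 20, 0, 40, 0, 20, 0, 40, 0)
  alt <- summarizeDisplacement(DisplacementTrace(0:10, v))
  expect_equal(sort(unique(alt$amplitudes)), c(20, 40))
  expect_equal(alt$mean, 30)
  expect_equal(alt$sd, stats::sd(alt$amplitudes))
})
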