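test_that("reference selection picks the extreme-height frame deterministically", {
  mkPlane <- function(hMm, id) TimedPointCloud(flatGrid(5, 10, hMm),
                                               timestamp = id, frameId = id)
  seqs <- list(mkPlane(0, 0L), mkPlane(5, 1L), mkPlane(2, 2L))
  expect_equal(frameId(selectReferenceCloud(seqs)), 1L)
  # inhalation decreasing the height coordinate flips the choice
  expect_equal(frameId(selectReferenceCloud(seqs, inhalationSign = -1)), 0L)
  # single frame and all-identical sequences
  expect_equal(frameId(selectReferenceCloud(seqs[2])), 1L)
  same <- list(mkPlane(3, 0L), mkPlane(3, 1L), mkPlane(3, 2L))
  expect_equal(frameId(selectReferenceCloud(same)), 0L)
  # index strategy and errors
  expect_equal(frameId(selectReferenceCloud(seqs, "index", index = 3)), 2L)
  expect_error(selectReferenceCloud(list()), "non-empty")
})

test_that("surrogate equals hand-computed nearest-neighbor means", {
  ref <- matrix(c(0, 0, 0, 1, 0, 0, 9, 9, 9), ncol = 3, byrow = TRUE)
  qu <- matrix(c(0, 0, 1, 1, 0, 2, 9, 9, 9), ncol = 3, byrow = TRUE)
  # nearest distances 1 m, 2 m, 0 m -> mean 1 m = 1000 mm
  expect_equal(computeSurrogate(qu, ref), 1000)
  expect_equal(computeSurrogate(ref, ref), 0)
  # flat grid translated 5 mm along its normal: interior-dominated exact 5 mm
  rest <- flatGrid(1, 10, 0)
  up <- flatGrid(1, 10, 5)
  expect_equal(computeSurrogate(up, rest), 5)
})

test_that("indexed surrogate matches the exhaustive oracle on random clouds", {
  set.seed(101)
  for (rep in 1:5) {
    n <- sample(5:200, 1)
    m <- sample(5:200, 1)
    ref <- matrix(rnorm(3 * m), ncol = 3)
    qu <- matrix(rnorm(3 * n), ncol = 3)
    expect_equal(computeSurrogate(qu, ref), bruteForceSurrogate(qu, ref))
  }
})

test_that("surrogate is permutation invariant and non-negative", {
  set.seed(7)
  ref <- matrix(rnorm(60), ncol = 3)
  qu <- matrix(rnorm(45), ncol = 3)
  v <- computeSurrogate(qu, ref)
  expect_gte(v, 0)
  expect_equal(computeSurrogate(qu[sample(nrow(qu)), ], ref[sample(nrow(ref)), ]), v)
})

test_that("surrogate series matches frame-wise brute force and copies timestamps", {
  set.seed(11)
  ref <- TimedPointCloud(matrix(rnorm(12), ncol = 3), 0, 0L)
  seqs <- lapply(1:3, function(i)
    TimedPointCloud(matrix(rnorm(12), ncol = 3), timestamp = i / 10,
                    frameId = i))
  ser <- computeSurrogateSeries(seqs, ref)
  expected <- vapply(seqs, function(cl)
    bruteForceSurrogate(cloudPoints(cl), cloudPoints(ref)), numeric(1))
  expect_equal(surrogateValues(ser), expected)
  expect_equal(timestamps(ser), c(0.1, 0.2, 0.3))
  expect_equal(frameId(ser), 0L)
  # identity: the sequence containing only the reference gives [0]
  expect_equal(surrogateValues(computeSurrogateSeries(list(ref), ref)), 0)
})

test_that("surrogate series tracks a known rigid elevation profile", {
  patch <- SurfacePatchModel(extent = 0.04, spacing = 0.002, bumpHeight = 0,
                             coupling = 1, depthNoiseSd = 0)
  elev <- c(5, 3, 1, 0, 2, 4)  # mm, maximum first frame
  tr <- DisplacementTrace(seq_along(elev) - 1, si = elev * 3, ap = elev)
  clouds <- simulateSurfaceSequence(tr, patch, rate = 1, duration = 6)
  ref <- selectReferenceCloud(clouds)
  expect_equal(frameId(ref), 0L)
  ser <- computeSurrogateSeries(clouds, ref)
  expect_equal(surrogateValues(ser), max(elev) - elev)
})

test_that("signed height-axis variant reproduces elevation with sign", {
  rest <- flatGrid(1, 6, 0)
  up <- flatGrid(1, 6, 4)
  # current 4 mm BELOW the reference, inhalation = +z
  expect_equal(computeSurrogate(rest, up, signed = TRUE), 4)
  expect_equal(computeSurrogate(up, rest, signed = TRUE), -4)
})
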