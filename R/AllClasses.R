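#' @useDynLib rimest, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

# ---------------------------------------------------------------------------
# Core data containers
# ---------------------------------------------------------------------------

#' Timestamped 3-D surface point cloud
#'
#' One observation of the abdominal (or phantom) surface: an unordered set of
#' 3-D points in meters, together with its acquisition timestamp and a frame
#' identifier. Sequences of these are the raw surrogate input.
#'
#' @slot points numeric matrix, N x 3, coordinates in meters.
#' @slot timestamp acquisition time in seconds.
#' @slot frameId integer frame identifier (0-based within a sequence).
#'
#' @examples
#' pc <- TimedPointCloud(matrix(rnorm(30), ncol = 3), timestamp = 0.5, frameId = 0L)
#' nPoints(pc)
#' @export TimedPointCloud
#' @exportClass TimedPointCloud
.TimedPointCloud <- setClass("TimedPointCloud",
  representation(points = "matrix", timestamp = "numeric", frameId = "integer"))

setValidity("TimedPointCloud", function(object) {
  p <- object@points
  if (!is.numeric(p) || ncol(p) != 3L)
    return("'points' must be a numeric N x 3 matrix")
  if (nrow(p) < 3L)
    return("a point cloud needs at least 3 points")
  if (!all(is.finite(p)))
    return("all point coordinates must be finite")
  if (length(object@timestamp) != 1L || !is.finite(object@timestamp))
    return("'timestamp' must be a single finite number")
  if (length(object@frameId) != 1L)
    return("'frameId' must be a single integer")
  TRUE
})

#' @param points numeric N x 3 matrix of coordinates in meters.
#' @param timestamp acquisition time in seconds.
#' @param frameId integer frame identifier.
#' @rdname TimedPointCloud-class
TimedPointCloud <- function(points, timestamp = 0, frameId = 0L) {
  .TimedPointCloud(points = as.matrix(points), timestamp = as.numeric(timestamp),
                   frameId = as.integer(frameId))
}

#' Maximum-inhalation reference cloud
#'
#' A [TimedPointCloud-class] promoted to the role of reference: every frame of
#' a sequence is compared against it to form the scalar surrogate. By default
#' the reference is the frame at maximum inhalation (extreme mean height along
#' the configured axis).
#'
#' @slot strategy character label of the selection strategy used.
#' @export ReferenceCloud
#' @exportClass ReferenceCloud
.ReferenceCloud <- setClass("ReferenceCloud",
  contains = "TimedPointCloud",
  representation(strategy = "character"))

#' @param cloud a [TimedPointCloud-class].
#' @param strategy selection strategy label.
#' @rdname ReferenceCloud-class
ReferenceCloud <- function(cloud, strategy = "index") {
  .ReferenceCloud(points = cloud@points, timestamp = cloud@timestamp,
                  frameId = cloud@frameId, strategy = as.character(strategy))
}

#' Scalar surrogate signal over time
#'
#' The regressor of the correspondence model: one scalar per surface frame,
#' in millimeters, here the mean distance from each point of the frame to its
#' closest point in the reference cloud.
#'
#' @slot timestamps seconds, strictly increasing.
#' @slot values surrogate values in mm (non-negative under the unsigned
#'   convention; may change sign under the signed height-axis variant).
#' @slot referenceFrameId frame id of the reference cloud.
#' @slot signed logical; TRUE if the signed height-axis convention was used.
#' @export SurrogateSeries
#' @exportClass SurrogateSeries
.SurrogateSeries <- setClass("SurrogateSeries",
  representation(timestamps = "numeric", values = "numeric",
                 referenceFrameId = "integer", signed = "logical"))

setValidity("SurrogateSeries", function(object) {
  if (length(object@timestamps) != length(object@values))
    return("'timestamps' and 'values' must have equal length")
  if (length(object@timestamps) > 1L && !anyNA(object@timestamps) &&
      any(diff(object@timestamps) <= 0))
    return("'timestamps' must be strictly increasing")
  if (!all(is.finite(object@values)))
    return("surrogate values must be finite")
  if (!object@signed && any(object@values < 0))
    return("unsigned surrogate values must be non-negative")
  TRUE
})

#' @param timestamps seconds.
#' @param values surrogate values in mm.
#' @param referenceFrameId frame id of the reference cloud.
#' @param signed logical, signed height-axis convention flag.
#' @rdname SurrogateSeries-class
SurrogateSeries <- function(timestamps, values, referenceFrameId = NA_integer_,
                            signed = FALSE) {
  .SurrogateSeries(timestamps = as.numeric(timestamps), values = as.numeric(values),
                   referenceFrameId = as.integer(referenceFrameId),
                   signed = isTRUE(signed))
}

#' Ground-truth displacement trace
#'
#' Timestamped 1-D internal displacement in millimeters. The
#' superior-inferior (SI) channel is always present; the anterior-posterior
#' (AP) channel is present for phantom-style traces and empty otherwise.
#'
#' @slot timestamps seconds, strictly increasing.
#' @slot si SI displacement, mm.
#' @slot ap AP displacement, mm (length 0 if absent).
#' @export DisplacementTrace
#' @exportClass DisplacementTrace
.DisplacementTrace <- setClass("DisplacementTrace",
  representation(timestamps = "numeric", si = "numeric", ap = "numeric"))

setValidity("DisplacementTrace", function(object) {
  n <- length(object@timestamps)
  if (length(object@si) != n)
    return("'si' must match 'timestamps' in length")
  if (length(object@ap) != 0L && length(object@ap) != n)
    return("'ap' must be empty or match 'timestamps' in length")
  if (n > 1L && any(diff(object@timestamps) <= 0))
    return("'timestamps' must be strictly increasing")
  if (!all(is.finite(object@si)) || !all(is.finite(object@ap)))
    return("displacements must be finite")
  TRUE
})

#' @param timestamps seconds.
#' @param si SI displacement in mm.
#' @param ap optional AP displacement in mm.
#' @rdname DisplacementTrace-class
DisplacementTrace <- function(timestamps, si, ap = numeric(0)) {
  .DisplacementTrace(timestamps = as.numeric(timestamps), si = as.numeric(si),
                     ap = as.numeric(ap))
}

#' Polynomial correspondence model
#'
#' The fitted mapping from surrogate x to internal displacement y:
#' y(x) = beta0 + beta1 x + ... + betan x^n, obtained by ordinary least
#' squares. Coefficients are stored on the original surrogate scale even
#' though fitting centers and scales x internally.
#'
#' @slot degree polynomial degree n.
#' @slot coefficients numeric vector beta of length degree + 1
#'   (intercept first), mm per mm^k.
#' @slot meta list of training metadata (regime, sessions, split, seed).
#' @export PolynomialModel
#' @exportClass PolynomialModel
.PolynomialModel <- setClass("PolynomialModel",
  representation(degree = "integer", coefficients = "numeric", meta = "list"))

setValidity("PolynomialModel", function(object) {
  if (length(object@coefficients) != object@degree + 1L)
    return("length(coefficients) must equal degree + 1")
  if (!all(is.finite(object@coefficients)))
    return("coefficients must be finite")
  TRUE
})

#' @param coefficients numeric beta vector, intercept first.
#' @param meta optional metadata list.
#' @rdname PolynomialModel-class
PolynomialModel <- function(coefficients, meta = list()) {
  .PolynomialModel(degree = length(coefficients) - 1L,
                   coefficients = as.numeric(coefficients), meta = meta)
}

#' One synchronized recording session
#'
#' Paired surrogate and ground-truth samples on a common, strictly
#' increasing timeline, with a per-sample breath-hold flag. Hold samples are
#' retained but flagged; model fitting and evaluation skip them.
#'
#' @slot sessionId integer session number.
#' @slot timestamps seconds.
#' @slot x surrogate values, mm.
#' @slot y ground-truth displacement, mm.
#' @slot hold logical; TRUE for samples inside a detected breath-hold.
#' @export SessionData
#' @exportClass SessionData
.SessionData <- setClass("SessionData",
  representation(sessionId = "integer", timestamps = "numeric",
                 x = "numeric", y = "numeric", hold = "logical"))

setValidity("SessionData", function(object) {
  n <- length(object@timestamps)
  if (length(object@x) != n || length(object@y) != n || length(object@hold) != n)
    return("'x', 'y' and 'hold' must match 'timestamps' in length")
  if (n > 1L && any(diff(object@timestamps) <= 0))
    return("'timestamps' must be strictly increasing")
  if (!all(is.finite(object@x)) || !all(is.finite(object@y)))
    return("x and y must be finite")
  TRUE
})

#' @param sessionId integer session number.
#' @param timestamps seconds.
#' @param x surrogate values, mm.
#' @param y displacement, mm.
#' @param hold logical breath-hold flags (default all FALSE).
#' @rdname SessionData-class
SessionData <- function(sessionId, timestamps, x, y,
                        hold = rep(FALSE, length(timestamps))) {
  .SessionData(sessionId = as.integer(sessionId), timestamps = as.numeric(timestamps),
               x = as.numeric(x), y = as.numeric(y), hold = as.logical(hold))
}

#' Binary segmentation mask
#'
#' A 2-D 0/1 mask of the liver in one ultrasound frame, with the isotropic
#' pixel spacing needed to convert pixel displacements into cm.
#'
#' @slot mask integer matrix of 0/1, row-major image coordinates (row, col),
#'   0-based indexing in all pixel-coordinate interfaces.
#' @slot pixelSpacing cm per pixel.
#' @slot timestamp seconds.
#' @export BinaryMask
#' @exportClass BinaryMask
.BinaryMask <- setClass("BinaryMask",
  representation(mask = "matrix", pixelSpacing = "numeric", timestamp = "numeric"))

setValidity("BinaryMask", function(object) {
  m <- object@mask
  if (!is.numeric(m) && !is.integer(m) && !is.logical(m))
    return("'mask' must be a numeric, integer or logical matrix")
  if (!all(m %in% c(0, 1)))
    return("'mask' must contain only 0 and 1")
  if (object@pixelSpacing <= 0)
    return("'pixelSpacing' must be positive")
  TRUE
})

#' @param mask 0/1 matrix.
#' @param pixelSpacing cm per pixel (default 0.027).
#' @param timestamp seconds.
#' @rdname BinaryMask-class
BinaryMask <- function(mask, pixelSpacing = 0.027, timestamp = 0) {
  storage.mode(mask) <- "integer"
  .BinaryMask(mask = mask, pixelSpacing = as.numeric(pixelSpacing),
              timestamp = as.numeric(timestamp))
}

#' Rectangular region of interest in pixel coordinates
#'
#' Half-open pixel ranges `[row0, row1) x [col0, col1)`, 0-based, used to
#' restrict edge tracking and Hausdorff evaluation to the liver border that
#' moves with respiration.
#'
#' @slot row0,row1,col0,col1 integer half-open ranges.
#' @export RoiBox
#' @exportClass RoiBox
.RoiBox <- setClass("RoiBox",
  representation(row0 = "integer", row1 = "integer",
                 col0 = "integer", col1 = "integer"))

setValidity("RoiBox", function(object) {
  if (object@row1 <= object@row0 || object@col1 <= object@col0)
    return("ROI ranges must be non-empty (half-open)")
  if (object@row0 < 0L || object@col0 < 0L)
    return("ROI ranges must be non-negative")
  TRUE
})

#' @param row0,row1,col0,col1 half-open 0-based pixel ranges.
#' @rdname RoiBox-class
RoiBox <- function(row0, row1, col0, col1) {
  .RoiBox(row0 = as.integer(row0), row1 = as.integer(row1),
          col0 = as.integer(col0), col1 = as.integer(col1))
}

#' Correspondence-model evaluation report
#'
#' Train/test mean absolute error (mm) and coefficient of determination (%)
#' for one training regime, with the per-session breakdown behind the
#' aggregate mean +/- sd rows.
#'
#' @slot regime "single", "specific" or "combined".
#' @slot degree polynomial degree used.
#' @slot train named numeric: mae, maeSd, r2, r2Sd (sd entries NA when the
#'   aggregate is a scalar).
#' @slot test named numeric, same layout.
#' @slot perSession data.frame with columns session, partition, mae, r2.
#' @slot models list of fitted [PolynomialModel-class] objects.
#' @exportClass ModelReport
.ModelReport <- setClass("ModelReport",
  representation(regime = "character", degree = "integer",
                 train = "numeric", test = "numeric",
                 perSession = "data.frame", models = "list"))

setValidity("ModelReport", function(object) {
  need <- c("mae", "maeSd", "r2", "r2Sd")
  if (!all(need %in% names(object@train)) || !all(need %in% names(object@test)))
    return("'train' and 'test' must contain mae, maeSd, r2, r2Sd")
  if (!is.na(object@train[["mae"]]) && object@train[["mae"]] < 0)
    return("MAE must be non-negative")
  TRUE
})

#' Paired surrogate / ground-truth streams before synchronization
#'
#' Holds the two asynchronous streams (surrogate at the camera rate,
#' ground truth at the tracker or ultrasound rate) plus alignment metadata
#' filled in by [synchronize()].
#'
#' @slot surrogate a [SurrogateSeries-class].
#' @slot groundTruth a [DisplacementTrace-class].
#' @slot offset applied time offset in seconds (ground-truth clock minus
#'   surrogate clock), NA before synchronization.
#' @export StreamPair
#' @exportClass StreamPair
.StreamPair <- setClass("StreamPair",
  representation(surrogate = "SurrogateSeries", groundTruth = "DisplacementTrace",
                 offset = "numeric"))

#' @param surrogate a [SurrogateSeries-class].
#' @param groundTruth a [DisplacementTrace-class].
#' @rdname StreamPair-class
StreamPair <- function(surrogate, groundTruth) {
  .StreamPair(surrogate = surrogate, groundTruth = groundTruth, offset = NA_real_)
}

# ---------------------------------------------------------------------------
# Simulator parameter objects
# ---------------------------------------------------------------------------

#' Breathing waveform parameters
#'
#' Kinematics of the simulated breathing motion. Amplitudes are
#' peak-to-trough; the waveform is either a pure sinusoid or a raised-cosine
#' power (sin^4) profile whose long exhale plateau better resembles real
#' breathing. Defaults are the phantom kinematics: 30 mm SI, 10 mm AP,
#' 0.25 Hz.
#'
#' @slot amplitudeSi,amplitudeAp peak-to-trough amplitudes, mm.
#' @slot frequency breathing frequency, Hz.
#' @slot waveform "raised-cosine-power" (default) or "sinusoid".
#' @slot noiseSd additive Gaussian noise on observed displacement, mm.
#' @slot seed integer RNG seed.
#' @export BreathingParams
#' @exportClass BreathingParams
.BreathingParams <- setClass("BreathingParams",
  representation(amplitudeSi = "numeric", amplitudeAp = "numeric",
                 frequency = "numeric", waveform = "character",
                 noiseSd = "numeric", seed = "integer"))

setValidity("BreathingParams", function(object) {
  if (object@amplitudeSi < 0 || object@amplitudeAp < 0)
    return("amplitudes must be non-negative")
  if (object@frequency <= 0)
    return("'frequency' must be positive")
  if (object@noiseSd < 0)
    return("'noiseSd' must be non-negative")
  if (!object@waveform %in% c("sinusoid", "raised-cosine-power"))
    return("'waveform' must be 'sinusoid' or 'raised-cosine-power'")
  TRUE
})

#' @param amplitudeSi,amplitudeAp peak-to-trough amplitudes in mm.
#' @param frequency breathing frequency in Hz.
#' @param waveform "raised-cosine-power" or "sinusoid".
#' @param noiseSd additive Gaussian noise sd in mm.
#' @param seed integer RNG seed.
#' @rdname BreathingParams-class
BreathingParams <- function(amplitudeSi = 30, amplitudeAp = 10, frequency = 0.25,
                            waveform = "raised-cosine-power", noiseSd = 0,
                            seed = 1L) {
  .BreathingParams(amplitudeSi = as.numeric(amplitudeSi),
                   amplitudeAp = as.numeric(amplitudeAp),
                   frequency = as.numeric(frequency),
                   waveform = as.character(waveform),
                   noiseSd = as.numeric(noiseSd), seed = as.integer(seed))
}

#' Per-session variability of a multi-session recording
#'
#' Inter-session drift applied to the base breathing parameters of one
#' subject: an amplitude multiplier, a baseline shift and a fractional
#' per-cycle period jitter.
#'
#' @slot amplitudeScale unitless multiplier (> 0).
#' @slot baselineShift mm added to the whole trace.
#' @slot frequencyJitter sd of the fractional per-cycle period perturbation.
#' @export SessionVariability
#' @exportClass SessionVariability
.SessionVariability <- setClass("SessionVariability",
  representation(amplitudeScale = "numeric", baselineShift = "numeric",
                 frequencyJitter = "numeric"))

setValidity("SessionVariability", function(object) {
  if (object@amplitudeScale <= 0)
    return("'amplitudeScale' must be positive")
  if (object@frequencyJitter < 0)
    return("'frequencyJitter' must be non-negative")
  TRUE
})

#' @param amplitudeScale unitless multiplier.
#' @param baselineShift mm.
#' @param frequencyJitter fractional per-cycle period sd.
#' @rdname SessionVariability-class
SessionVariability <- function(amplitudeScale = 1, baselineShift = 0,
                               frequencyJitter = 0) {
  .SessionVariability(amplitudeScale = as.numeric(amplitudeScale),
                      baselineShift = as.numeric(baselineShift),
                      frequencyJitter = as.numeric(frequencyJitter))
}

#' Abdominal surface patch model
#'
#' The deforming surface observed by the depth camera: a square grid of
#' points in meters, a smooth Gaussian-bump rest height profile, and a
#' coupling that raises the surface by `coupling` mm per mm of internal AP
#' displacement. Per-point Gaussian depth noise emulates a consumer depth
#' camera (default 1 mm sd).
#'
#' @slot extent grid side length, m.
#' @slot spacing grid spacing, m.
#' @slot bumpHeight rest bump height at the patch center, m.
#' @slot bumpSigma Gaussian bump width, m.
#' @slot coupling mm of surface elevation per mm of AP displacement (non-zero).
#' @slot depthNoiseSd per-point depth noise sd, m.
#' @export SurfacePatchModel
#' @exportClass SurfacePatchModel
.SurfacePatchModel <- setClass("SurfacePatchModel",
  representation(extent = "numeric", spacing = "numeric", bumpHeight = "numeric",
                 bumpSigma = "numeric", coupling = "numeric",
                 depthNoiseSd = "numeric"))

setValidity("SurfacePatchModel", function(object) {
  if (object@spacing <= 0) return("'spacing' must be positive")
  if (object@extent < object@spacing) return("'extent' must cover the grid")
  if (object@coupling == 0) return("'coupling' must be non-zero")
  if (object@depthNoiseSd < 0) return("'depthNoiseSd' must be non-negative")
  TRUE
})

#' @param extent grid side length in m.
#' @param spacing grid spacing in m.
#' @param bumpHeight rest bump height in m.
#' @param bumpSigma bump width in m.
#' @param coupling mm surface elevation per mm AP displacement.
#' @param depthNoiseSd per-point depth noise sd in m (default 1 mm).
#' @rdname SurfacePatchModel-class
SurfacePatchModel <- function(extent = 0.24, spacing = 0.01, bumpHeight = 0.05,
                              bumpSigma = 0.08, coupling = 1,
                              depthNoiseSd = 0.001) {
  .SurfacePatchModel(extent = as.numeric(extent), spacing = as.numeric(spacing),
                     bumpHeight = as.numeric(bumpHeight),
                     bumpSigma = as.numeric(bumpSigma),
                     coupling = as.numeric(coupling),
                     depthNoiseSd = as.numeric(depthNoiseSd))
}

#' Multi-session recording protocol
#'
#' The clinical-style acquisition protocol: sessions of fixed duration whose
#' first and last `breathholdDuration` seconds are flat breath-holds, a
#' surrogate stream at the camera rate and a ground-truth stream at the
#' tracker/ultrasound rate.
#'
#' @slot sessionDuration seconds (breath-holds included).
#' @slot nSessions number of sessions.
#' @slot breathholdDuration seconds of flat hold at each end (0 disables).
#' @slot surrogateRate Hz.
#' @slot groundtruthRate Hz.
#' @export ProtocolSpec
#' @exportClass ProtocolSpec
.ProtocolSpec <- setClass("ProtocolSpec",
  representation(sessionDuration = "numeric", nSessions = "integer",
                 breathholdDuration = "numeric", surrogateRate = "numeric",
                 groundtruthRate = "numeric"))

setValidity("ProtocolSpec", function(object) {
  if (object@sessionDuration <= 0) return("'sessionDuration' must be positive")
  if (object@nSessions < 1L) return("'nSessions' must be >= 1")
  if (object@breathholdDuration < 0) return("'breathholdDuration' must be >= 0")
  if (2 * object@breathholdDuration >= object@sessionDuration)
    return("breath-holds must leave room for free breathing")
  if (object@surrogateRate <= 0 || object@groundtruthRate <= 0)
    return("rates must be positive")
  TRUE
})

#' @param sessionDuration seconds.
#' @param nSessions number of sessions.
#' @param breathholdDuration seconds of hold at each end.
#' @param surrogateRate surrogate sampling rate, Hz.
#' @param groundtruthRate ground-truth sampling rate, Hz.
#' @rdname ProtocolSpec-class
ProtocolSpec <- function(sessionDuration = 60, nSessions = 3L,
                         breathholdDuration = 5, surrogateRate = 30,
                         groundtruthRate = 15) {
  .ProtocolSpec(sessionDuration = as.numeric(sessionDuration),
                nSessions = as.integer(nSessions),
                breathholdDuration = as.numeric(breathholdDuration),
                surrogateRate = as.numeric(surrogateRate),
                groundtruthRate = as.numeric(groundtruthRate))
}
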