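# Synthetic phantom and multi-session clinical datasets: breathing traces,
# deforming surface point clouds, and liver mask sequences with a moving
# right edge. Every downstream stage of the pipeline is testable on these.

# Evaluate an expression with a temporary RNG seed, restoring global state.
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  expr
}

# Normalized cycle shape on u in [0, 1]: 0 at cycle start (end-exhale),
# 1 at mid-cycle (peak inhalation).
.cycleShape <- function(u, waveform) {
  switch(waveform,
         "sinusoid" = (1 - cos(2 * pi * u)) / 2,
         "raised-cosine-power" = sin(pi * u)^4,
         stop("unknown waveform: ", waveform))
}

# Closure s(t) in [0, 1] for one session: cycle-by-cycle evaluation with
# optional per-cycle period jitter, flat at 0 outside [holdAt, holdUntil].
.sessionShapeFun <- function(frequency, waveform, duration,
                             holdDuration = 0, frequencyJitter = 0,
                             jitterSeed = NULL) {
  t0 <- holdDuration
  t1 <- duration - holdDuration
  baseT <- 1 / frequency
  span <- t1 - t0
  nCycles <- ceiling(span / baseT) + 2L
  mult <- rep(1, nCycles)
  if (frequencyJitter > 0) {
    if (is.null(jitterSeed))
      stop("'jitterSeed' is required when frequencyJitter > 0")
    mult <- .withSeed(jitterSeed,
                      pmax(0.2, 1 + stats::rnorm(nCycles, 0, frequencyJitter)))
  }
  periods <- baseT * mult
  bounds <- t0 + c(0, cumsum(periods))
  function(t) {
    s <- numeric(length(t))
    inside <- t > t0 & t < t1
    if (any(inside)) {
      k <- findInterval(t[inside], bounds)
      k <- pmin(pmax(k, 1L), length(periods))
      u <- (t[inside] - bounds[k]) / periods[k]
      s[inside] <- .cycleShape(pmin(pmax(u, 0), 1), waveform)
    }
    s
  }
}

#' Simulate a breathing displacement trace
#'
#' Generates the internal liver motion of the robotic phantom or of a
#' simulated subject: SI and AP channels oscillating with the configured
#' peak-to-trough amplitudes and frequency, plus additive Gaussian
#' observation noise. The waveform starts and ends at end-exhale (value 0),
#' and peaks reach the full configured amplitude.
#'
#' @param params a [BreathingParams-class].
#' @param duration trace duration in seconds.
#' @param rate sampling rate in Hz.
#' @param baselineShift mm added to the SI channel (inter-session drift).
#' @param holdDuration seconds of flat end-exhale breath-hold at each end of
#'   the trace (0 = none, the phantom case).
#' @param frequencyJitter sd of the fractional per-cycle period perturbation.
#' @return a [DisplacementTrace-class] with SI and AP channels in mm.
#' @examples
#' tr <- simulateBreathingTrace(BreathingParams(noiseSd = 0), 60, 30)
#' max(siValues(tr)) - min(siValues(tr))  # 30 mm peak-to-trough
#' @export
simulateBreathingTrace <- function(params, duration, rate, baselineShift = 0,
                                   holdDuration = 0, frequencyJitter = 0) {
  stopifnot(is(params, "BreathingParams"))
  if (duration <= 0 || rate <= 0)
    stop("'duration' and 'rate' must be positive")
  n <- round(duration * rate)
  if (n < 2L) stop("duration * rate must yield at least 2 samples")
  tt <- (seq_len(n) - 1L) / rate
  sfun <- .sessionShapeFun(params@frequency, params@waveform, duration,
                           holdDuration = holdDuration,
                           frequencyJitter = frequencyJitter,
                           jitterSeed = params@seed + 104729L)
  s <- sfun(tt)
  si <- baselineShift + params@amplitudeSi * s
  ap <- params@amplitudeAp * s
  if (params@noiseSd > 0) {
    noise <- .withSeed(params@seed, matrix(stats::rnorm(2L * n, 0, params@noiseSd), ncol = 2L))
    si <- si + noise[, 1L]
    ap <- ap + noise[, 2L]
  }
  DisplacementTrace(tt, si, ap)
}

#' Simulate a deforming abdominal-surface point-cloud sequence
#'
#' Builds one surface observation per frame: a square grid patch with a
#' smooth Gaussian rest bump, elevated along the height (z) axis by
#' `coupling` mm per mm of the trace's AP displacement, with optional
#' per-point Gaussian depth noise. The point count is constant across
#' frames and timestamps are spaced at 1/rate.
#'
#' @param trace a [DisplacementTrace-class] whose AP channel drives the
#'   surface (must cover the requested span).
#' @param patch a [SurfacePatchModel-class].
#' @param rate cloud frame rate, Hz.
#' @param duration span to cover in seconds (default: the trace's span).
#' @param seed RNG seed for depth noise.
#' @return list of [TimedPointCloud-class], coordinates in meters.
#' @export
simulateSurfaceSequence <- function(trace, patch, rate, duration = NULL,
                                    seed = 1L) {
  stopifnot(is(trace, "DisplacementTrace"), is(patch, "SurfacePatchModel"))
  tt0 <- timestamps(trace)
  if (length(tt0) == 0L) stop("'trace' is empty")
  if (length(apValues(trace)) == 0L) stop("'trace' has no AP channel")
  if (rate <= 0) stop("'rate' must be positive")
  if (is.null(duration)) duration <- max(tt0) - min(tt0)
  n <- max(2L, round(duration * rate))
  tt <- min(tt0) + (seq_len(n) - 1L) / rate
  if (max(tt) > max(tt0) + 1e-9)
    stop("'trace' does not cover the requested time span")
  apAt <- stats::approx(tt0, apValues(trace), xout = tt, rule = 2)$y
  g <- seq(-patch@extent / 2, patch@extent / 2, by = patch@spacing)
  xy <- as.matrix(expand.grid(x = g, y = g))
  rest <- patch@bumpHeight * exp(-(xy[, 1L]^2 + xy[, 2L]^2) / (2 * patch@bumpSigma^2))
  m <- nrow(xy)
  .withSeed(seed, {
    lapply(seq_len(n), function(i) {
      z <- rest + patch@coupling * apAt[i] * 1e-3
      if (patch@depthNoiseSd > 0)
        z <- z + stats::rnorm(m, 0, patch@depthNoiseSd)
      TimedPointCloud(cbind(xy, z = z), timestamp = tt[i], frameId = i - 1L)
    })
  })
}

#' Simulate a binary liver-mask sequence
#'
#' Generates one filled single-component mask per trace sample. The mask's
#' right edge column follows the SI displacement:
#' `column = rest column + round(SI(t) / 10 / pixelSpacing)` (SI in mm,
#' spacing in cm/px), so edge tracking along the image x-axis recovers the
#' trace up to pixel rounding.
#'
#' @param trace a [DisplacementTrace-class] (SI channel used).
#' @param imageSize integer c(rows, cols).
#' @param pixelSpacing cm per pixel (default 0.027).
#' @param restColumn rest position of the right edge (0-based column), or
#'   NULL to center the excursion automatically.
#' @param leftColumn fixed left edge of the filled region (0-based).
#' @param rowBand integer c(row0, row1), half-open row extent of the region;
#'   default: the middle 60 percent of the image.
#' @param edgeShape optional integer offsets (one per band row) added to the
#'   rest column, giving the liver border a non-straight profile.
#' @return list of [BinaryMask-class].
#' @export
simulateMaskSequence <- function(trace, imageSize = c(256L, 384L),
                                 pixelSpacing = 0.027, restColumn = NULL,
                                 leftColumn = 8L, rowBand = NULL,
                                 edgeShape = NULL) {
  stopifnot(is(trace, "DisplacementTrace"))
  si <- siValues(trace)
  if (length(si) == 0L) stop("'trace' is empty")
  nr <- as.integer(imageSize[1L]); nc <- as.integer(imageSize[2L])
  shiftPx <- round(si / 10 / pixelSpacing)
  if (is.null(rowBand))
    rowBand <- c(floor(0.2 * nr), ceiling(0.8 * nr))
  rows <- seq.int(rowBand[1L], rowBand[2L] - 1L)
  if (is.null(edgeShape)) edgeShape <- rep(0L, length(rows))
  if (length(edgeShape) != length(rows))
    stop("'edgeShape' must have one offset per band row")
  if (is.null(restColumn)) {
    lo <- leftColumn + 2L - min(shiftPx + min(edgeShape))
    hi <- nc - 2L - max(shiftPx + max(edgeShape))
    if (hi < lo) stop("trace excursion does not fit inside the image")
    restColumn <- floor((lo + hi) / 2)
  }
  edges <- outer(edgeShape + restColumn, shiftPx, "+")  # band rows x frames
  if (min(edges) <= leftColumn || max(edges) >= nc - 1L)
    stop("trace excursion does not fit inside the image")
  tt <- timestamps(trace)
  lapply(seq_along(si), function(i) {
    m <- matrix(0L, nr, nc)
    for (j in seq_along(rows))
      m[rows[j] + 1L, (leftColumn + 1L):(edges[j, i] + 1L)] <- 1L
    BinaryMask(m, pixelSpacing = pixelSpacing, timestamp = tt[i])
  })
}

#' Simulate a multi-session recording set
#'
#' Generates the raw material for the three-regime clinical analysis: for
#' each session, a ground-truth displacement trace at the ground-truth rate
#' (with flat end-exhale breath-holds at both ends and per-session amplitude
#' scale, baseline shift and period jitter), plus optionally the surface
#' point-cloud sequence at the surrogate rate and the liver-mask sequence.
#' Session k's RNG seed is `params@seed + k`, so sessions are independent
#' but the whole set regenerates bit-identically from one master seed.
#'
#' @param params base [BreathingParams-class] of the subject.
#' @param protocol a [ProtocolSpec-class].
#' @param variability list of [SessionVariability-class], one per session.
#' @param patch a [SurfacePatchModel-class] used when `clouds = TRUE`.
#' @param clouds logical; generate surface sequences (default TRUE).
#' @param masks logical; generate mask sequences (default FALSE — they are
#'   large and only needed for edge-tracking studies).
#' @param maskArgs list of extra arguments for [simulateMaskSequence()].
#' @return list with one element per session: list(sessionId, trace, clouds,
#'   masks, holdWindows) where holdWindows is a data.frame(start, end) in
#'   seconds.
#' @export
simulateSessionSet <- function(params, protocol, variability,
                               patch = SurfacePatchModel(), clouds = TRUE,
                               masks = FALSE, maskArgs = list()) {
  stopifnot(is(params, "BreathingParams"), is(protocol, "ProtocolSpec"))
  if (length(variability) != protocol@nSessions)
    stop("need exactly one SessionVariability per session (",
         protocol@nSessions, ")")
  lapply(seq_len(protocol@nSessions), function(k) {
    v <- variability[[k]]
    stopifnot(is(v, "SessionVariability"))
    sessSeed <- params@seed + k
    sessParams <- BreathingParams(
      amplitudeSi = params@amplitudeSi * v@amplitudeScale,
      amplitudeAp = params@amplitudeAp * v@amplitudeScale,
      frequency = params@frequency, waveform = params@waveform,
      noiseSd = params@noiseSd, seed = sessSeed)
    trace <- simulateBreathingTrace(
      sessParams, protocol@sessionDuration, protocol@groundtruthRate,
      baselineShift = v@baselineShift,
      holdDuration = protocol@breathholdDuration,
      frequencyJitter = v@frequencyJitter)
    cl <- NULL
    if (isTRUE(clouds)) {
      # the surface follows the noiseless AP motion; depth noise is the
      # patch's own observation model
      clean <- simulateBreathingTrace(
        BreathingParams(sessParams@amplitudeSi, sessParams@amplitudeAp,
                        sessParams@frequency, sessParams@waveform,
                        noiseSd = 0, seed = sessSeed),
        protocol@sessionDuration, protocol@surrogateRate,
        holdDuration = protocol@breathholdDuration,
        frequencyJitter = v@frequencyJitter)
      cl <- simulateSurfaceSequence(clean, patch, protocol@surrogateRate,
                                    seed = sessSeed + 7919L)
    }
    mk <- NULL
    if (isTRUE(masks))
      mk <- do.call(simulateMaskSequence, c(list(trace = trace), maskArgs))
    hw <- data.frame(
      start = c(0, protocol@sessionDuration - protocol@breathholdDuration),
      end = c(protocol@breathholdDuration, protocol@sessionDuration))
    if (protocol@breathholdDuration == 0) hw <- hw[0L, ]
    list(sessionId = k, trace = trace, clouds = cl, masks = mk,
         holdWindows = hw)
  })
}

#' Dominant frequency of a sampled signal
#'
#' Location of the largest non-DC peak of the discrete Fourier magnitude
#' spectrum, at the resolution rate/length.
#'
#' @param values numeric signal samples.
#' @param rate sampling rate in Hz.
#' @return frequency in Hz.
#' @export
dominantFrequency <- function(values, rate) {
  n <- length(values)
  if (n < 4L) stop("signal too short for a spectrum")
  mag <- Mod(stats::fft(values))
  half <- 2:(floor(n / 2) + 1L)
  k <- half[which.max(mag[half])]
  (k - 1L) * rate / n
}
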