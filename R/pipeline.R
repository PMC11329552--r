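# Stream synchronization and end-to-end experiment orchestration: the
# phantom experiment (specific regime, SI + AP axes) and the multi-session
# clinical analog (single / specific / combined regimes per subject with
# subject-mean overall rows).

#' Detect breath-hold windows in a displacement or surrogate signal
#'
#' A sliding window is flagged when its sample variance is at or below the
#' threshold; flagged windows are merged into hold intervals. The default
#' threshold adapts to the signal (5 percent of its global variance), which
#' separates flat holds from breathing for any amplitude scale as long as
#' measurement noise is small against the breathing amplitude.
#'
#' @param values signal samples, mm.
#' @param timestamps seconds (regular sampling assumed).
#' @param window window length in seconds (default 2).
#' @param varianceThreshold mm^2; NULL (default) for the adaptive rule.
#' @param minDuration seconds a candidate must persist to count as a hold
#'   (default 3). Breathing waveforms with long exhale plateaus otherwise
#'   masquerade as short holds at every cycle trough.
#' @return data.frame(start, end) in seconds; zero rows when no hold.
#' @export
detectBreathholds <- function(values, timestamps, window = 2,
                              varianceThreshold = NULL, minDuration = 3) {
  n <- length(values)
  stopifnot(n == length(timestamps), n >= 2L)
  dt <- stats::median(diff(timestamps))
  w <- max(2L, round(window / dt))
  if (n < 2L * w) stop("trace must be at least twice the window length")
  if (is.null(varianceThreshold))
    varianceThreshold <- 0.05 * stats::var(values)
  s1 <- cumsum(c(0, values))
  s2 <- cumsum(c(0, values^2))
  starts <- seq_len(n - w + 1L)
  sm <- s1[starts + w] - s1[starts]
  sq <- s2[starts + w] - s2[starts]
  v <- pmax(0, (sq - sm^2 / w) / (w - 1L))
  cover <- logical(n)
  for (i in which(v <= varianceThreshold))
    cover[i:(i + w - 1L)] <- TRUE
  if (!any(cover)) return(data.frame(start = numeric(0), end = numeric(0)))
  r <- rle(cover)
  hi <- cumsum(r$lengths)
  lo <- hi - r$lengths + 1L
  keep <- which(r$values)
  out <- data.frame(start = timestamps[lo[keep]], end = timestamps[hi[keep]])
  out[out$end - out$start >= minDuration, , drop = FALSE]
}

# Sub-sample estimate of when a stream leaves its leading hold: the
# interpolated time its deviation from the hold level first exceeds a
# fixed fraction of the stream's range. Both streams are (to noise) affine
# in the same breathing shape, so the fractional threshold is crossed at
# the same physical instant in both, independent of units and sampling.
.holdExitTime <- function(v, tt, holdStart, holdEnd, frac = 0.25) {
  inHold <- tt >= holdStart & tt <= holdEnd
  lvl <- stats::median(v[inHold])
  dev <- abs(v - lvl)
  thr <- frac * (max(v) - min(v))
  i0 <- which(inHold)[1L]
  cand <- which(dev > thr & seq_along(v) >= i0)
  if (length(cand) == 0L) return(holdEnd)
  i <- cand[1L]
  if (i == 1L) return(tt[1L])
  t0 <- tt[i - 1L]
  d0 <- dev[i - 1L]
  t0 + (thr - d0) / (dev[i] - d0) * (tt[i] - t0)
}

#' Synchronize a surrogate / ground-truth stream pair
#'
#' Puts both streams on the surrogate timeline. With `method =
#' "timestamps"` the ground truth is linearly interpolated onto the
#' surrogate timestamps within the overlapping support (no extrapolation).
#' With `method = "breathholds"` a constant clock offset is first estimated
#' by aligning the end of the leading breath-hold detected in each stream
#' (located to sub-sample precision as the interpolated time the signal
#' departs from its hold level by a fixed fraction of its range), then
#' interpolation proceeds as above; samples inside hold windows are
#' flagged (not deleted) and skipped by model fitting and scoring.
#'
#' @param pair a [StreamPair-class].
#' @param method "timestamps" or "breathholds".
#' @param sessionId session id recorded in the result.
#' @param channel ground-truth channel, "si" (default) or "ap".
#' @param holdWindow,holdVarianceThreshold hold-detection settings (see
#'   [detectBreathholds()]).
#' @return a [SessionData-class]; the applied offset (ground-truth clock
#'   minus surrogate clock, seconds) is available as `attr(, "offset")` and
#'   the synchronized pair as `attr(, "pair")`.
#' @export
synchronize <- function(pair, method = c("timestamps", "breathholds"),
                        sessionId = 1L, channel = c("si", "ap"),
                        holdWindow = 2, holdVarianceThreshold = NULL) {
  method <- match.arg(method)
  channel <- match.arg(channel)
  stopifnot(is(pair, "StreamPair"))
  st <- timestamps(pair@surrogate)
  sv <- surrogateValues(pair@surrogate)
  gt <- timestamps(pair@groundTruth)
  gv <- if (channel == "si") siValues(pair@groundTruth) else
    apValues(pair@groundTruth)
  if (length(gv) == 0L) stop("ground truth has no ", toupper(channel), " channel")
  offset <- 0
  holds <- data.frame(start = numeric(0), end = numeric(0))
  if (method == "breathholds") {
    hs <- detectBreathholds(sv, st, holdWindow, holdVarianceThreshold)
    hg <- detectBreathholds(gv, gt, holdWindow, holdVarianceThreshold)
    if (nrow(hs) == 0L || nrow(hg) == 0L)
      stop("breath-hold synchronization requires a detectable hold in both streams")
    offset <- .holdExitTime(sv, st, hs$start[1L], hs$end[1L]) -
      .holdExitTime(gv, gt, hg$start[1L], hg$end[1L])
    holds <- hs
  }
  gtShifted <- gt + offset
  lo <- max(min(st), min(gtShifted))
  hi <- min(max(st), max(gtShifted))
  if (lo >= hi) stop("streams have no overlapping time support")
  keep <- st >= lo & st <= hi
  if (!any(keep)) stop("streams have no overlapping time support")
  tt <- st[keep]
  y <- stats::approx(gtShifted, gv, xout = tt)$y
  hold <- rep(FALSE, length(tt))
  if (method == "breathholds") {
    # flag holds seen in either stream, on the surrogate clock
    hAll <- rbind(holds, data.frame(start = hg$start + offset,
                                    end = hg$end + offset))
    for (k in seq_len(nrow(hAll)))
      hold <- hold | (tt >= hAll$start[k] & tt <= hAll$end[k])
  }
  out <- SessionData(sessionId, tt, sv[keep], y, hold)
  attr(out, "offset") <- offset
  syncedPair <- pair
  syncedPair@offset <- offset
  attr(out, "pair") <- syncedPair
  out
}

# Direct (geometry-free) surrogate of a session: coupling * (max AP - AP(t))
# on the surrogate timeline — what the cloud pipeline measures, without
# building clouds. Used by the fast experiment mode.
.directSurrogate <- function(cleanTrace, coupling = 1) {
  ap <- apValues(cleanTrace)
  SurrogateSeries(timestamps(cleanTrace), coupling * (max(ap) - ap),
                  referenceFrameId = which.max(ap) - 1L, signed = FALSE)
}

# Seeded Gaussian noise on the surrogate channel of a synchronized session.
.addSurrogateNoise <- function(session, sd, seed) {
  if (sd <= 0) return(session)
  noise <- .withSeed(seed, stats::rnorm(length(session@x), 0, sd))
  SessionData(session@sessionId, session@timestamps, session@x + noise,
              session@y, session@hold)
}

#' Run the phantom experiment end-to-end
#'
#' Simulates the robotic phantom (periodic motion: 30 mm SI, 10 mm AP
#' peak-to-trough at 0.25 Hz by default), computes the surrogate, and fits
#' specific-regime models — one per motion axis, as only the specific model
#' is meaningful for strictly periodic motion. Returns train/test MAE and
#' R^2 per axis.
#'
#' @param config list; recognized fields (with defaults):
#'   `duration` (60 s), `surrogateRate` (30 Hz), `groundtruthRate` (40 Hz),
#'   `params` ([BreathingParams-class]), `patch` ([SurfacePatchModel-class]),
#'   `degree` (3), `trainFraction` (0.7), `surrogateNoiseSd` (0 mm),
#'   `surrogateMode` ("pointcloud" or "direct"), `seed` (required when any
#'   noise source is active).
#' @return list(si, ap) of [ModelReport-class], plus `table` (data.frame)
#'   and `sessions` (the synchronized per-axis [SessionData-class]).
#' @export
runPhantomExperiment <- function(config = list()) {
  cfg <- utils::modifyList(list(
    duration = 60, surrogateRate = 30, groundtruthRate = 40,
    params = BreathingParams(), patch = SurfacePatchModel(depthNoiseSd = 0),
    degree = 3L, trainFraction = 0.7, surrogateNoiseSd = 0,
    surrogateMode = "pointcloud", seed = NULL), config)
  stochastic <- cfg$surrogateNoiseSd > 0 || cfg$params@noiseSd > 0 ||
    cfg$patch@depthNoiseSd > 0
  if (stochastic && is.null(cfg$seed))
    stop("a 'seed' is required when any noise source is active")
  seed <- if (is.null(cfg$seed)) 0L else as.integer(cfg$seed)
  params <- cfg$params
  params@seed <- seed
  gtTrace <- simulateBreathingTrace(params, cfg$duration, cfg$groundtruthRate)
  clean <- simulateBreathingTrace(
    BreathingParams(params@amplitudeSi, params@amplitudeAp, params@frequency,
                    params@waveform, noiseSd = 0, seed = seed),
    cfg$duration, cfg$surrogateRate)
  surr <- if (identical(cfg$surrogateMode, "direct")) {
    .directSurrogate(clean, cfg$patch@coupling)
  } else {
    clouds <- simulateSurfaceSequence(clean, cfg$patch, cfg$surrogateRate,
                                      seed = seed + 7919L)
    ref <- selectReferenceCloud(clouds)
    computeSurrogateSeries(clouds, ref)
  }
  fitAxis <- function(channel) {
    sess <- synchronize(StreamPair(surr, gtTrace), "timestamps",
                        channel = channel)
    sess <- .addSurrogateNoise(sess, cfg$surrogateNoiseSd,
                               seed + if (channel == "si") 11L else 13L)
    runSpecificModel(sess, degree = cfg$degree,
                     trainFraction = cfg$trainFraction)
  }
  si <- fitAxis("si")
  ap <- fitAxis("ap")
  tab <- rbind(cbind(axis = "SI", reportTable(si)),
               cbind(axis = "AP", reportTable(ap)))
  list(si = si, ap = ap, table = tab)
}

# Build the synchronized sessions of one simulated subject.
.simulateSubjectSessions <- function(params, protocol, variability, patch,
                                     surrogateMode, surrogateNoiseSd,
                                     syncMethod = "breathholds",
                                     coupling = 1) {
  raw <- simulateSessionSet(params, protocol, variability, patch = patch,
                            clouds = identical(surrogateMode, "pointcloud"),
                            masks = FALSE)
  lapply(raw, function(sess) {
    surr <- if (identical(surrogateMode, "pointcloud")) {
      ref <- selectReferenceCloud(sess$clouds)
      computeSurrogateSeries(sess$clouds, ref)
    } else {
      clean <- simulateBreathingTrace(
        BreathingParams(params@amplitudeSi, params@amplitudeAp,
                        params@frequency, params@waveform, noiseSd = 0,
                        seed = params@seed + sess$sessionId),
        protocol@sessionDuration, protocol@surrogateRate,
        holdDuration = protocol@breathholdDuration)
      .directSurrogate(clean, coupling)
    }
    sd <- synchronize(StreamPair(surr, sess$trace), syncMethod,
                      sessionId = sess$sessionId)
    .addSurrogateNoise(sd, surrogateNoiseSd,
                       params@seed + 31L * sess$sessionId)
  })
}

#' Run the multi-session clinical-analog experiment end-to-end
#'
#' Simulates a cohort of subjects, three sessions each with inter-session
#' amplitude/baseline drift, runs the three training regimes per subject,
#' and aggregates overall rows as the mean +/- sd across subjects of the
#' per-subject values (equal subject weighting).
#'
#' @param config list; recognized fields (defaults): `nSubjects` (6),
#'   `protocol` ([ProtocolSpec-class]), `amplitudeRange` (c(20, 50) mm SI,
#'   drawn per subject), `apRatio` (AP amplitude = SI / 3),
#'   `sessionScales` (c(1.0, 0.9, 1.1)), `baselineShiftMax` (3 mm, drawn
#'   uniformly in +/- max per session), `frequency` (0.25 Hz), `waveform`,
#'   `patch`, `surrogateNoiseSd` (1 mm), `degree` (3), `trainFraction`
#'   (0.7), `surrogateMode` ("direct" or "pointcloud"), `syncMethod`
#'   ("breathholds"), `seed` (required).
#' @return list(perSubject = list of list(single, specific, combined),
#'   overall = data.frame(regime, partition, metric, mean, sd),
#'   subjects = data.frame of drawn subject parameters).
#' @export
runClinicalExperiment <- function(config = list()) {
  cfg <- utils::modifyList(list(
    nSubjects = 6L, protocol = ProtocolSpec(),
    amplitudeRange = c(20, 50), apRatio = 1 / 3,
    sessionScales = c(1.0, 0.9, 1.1), baselineShiftMax = 3,
    frequency = 0.25, waveform = "raised-cosine-power",
    patch = SurfacePatchModel(depthNoiseSd = 0), surrogateNoiseSd = 1,
    degree = 3L, trainFraction = 0.7, surrogateMode = "direct",
    syncMethod = "breathholds", seed = NULL), config)
  if (is.null(cfg$seed)) stop("a 'seed' is required")
  seed <- as.integer(cfg$seed)
  proto <- cfg$protocol
  if (length(cfg$sessionScales) != proto@nSessions)
    stop("'sessionScales' must have one entry per session")
  draws <- .withSeed(seed, list(
    amp = stats::runif(cfg$nSubjects, cfg$amplitudeRange[1L],
                       cfg$amplitudeRange[2L]),
    shifts = matrix(stats::runif(cfg$nSubjects * proto@nSessions,
                                 -cfg$baselineShiftMax, cfg$baselineShiftMax),
                    nrow = cfg$nSubjects)))
  perSubject <- vector("list", cfg$nSubjects)
  for (i in seq_len(cfg$nSubjects)) {
    params <- BreathingParams(draws$amp[i], draws$amp[i] * cfg$apRatio,
                              cfg$frequency, cfg$waveform, noiseSd = 0,
                              seed = seed + 1000L * i)
    variability <- lapply(seq_len(proto@nSessions), function(k)
      SessionVariability(amplitudeScale = cfg$sessionScales[k],
                         baselineShift = draws$shifts[i, k]))
    sessions <- .simulateSubjectSessions(
      params, proto, variability, cfg$patch, cfg$surrogateMode,
      cfg$surrogateNoiseSd, syncMethod = cfg$syncMethod,
      coupling = cfg$patch@coupling)
    perSubject[[i]] <- list(
      single = runSingleModel(sessions, cfg$degree),
      specific = runSpecificModel(sessions, cfg$degree, cfg$trainFraction),
      combined = runCombinedModel(sessions, cfg$degree, cfg$trainFraction))
  }
  overall <- do.call(rbind, lapply(c("single", "specific", "combined"),
                                   function(regime) {
    do.call(rbind, lapply(c("train", "test"), function(part) {
      vals <- vapply(perSubject, function(ps) {
        v <- if (part == "train") ps[[regime]]@train else ps[[regime]]@test
        c(v[["mae"]], v[["r2"]])
      }, numeric(2))
      data.frame(regime = regime, partition = part,
                 metric = c("MAE_mm", "R2_pct"),
                 mean = c(mean(vals[1L, ]), mean(vals[2L, ])),
                 sd = c(stats::sd(vals[1L, ]), stats::sd(vals[2L, ])))
    }))
  }))
  list(perSubject = perSubject, overall = overall,
       subjects = data.frame(subject = seq_len(cfg$nSubjects),
                             amplitudeSi = draws$amp,
                             amplitudeAp = draws$amp * cfg$apRatio))
}

#' Summarize liver displacement across a cohort
#'
#' Per-session peak-to-trough amplitude summaries (via
#' [summarizeDisplacement()]) and the overall mean and sample (n-1)
#' standard deviation over the per-session mean amplitudes, equally
#' weighting sessions.
#'
#' @param x either a nested list (subjects, then sessions) of
#'   [DisplacementTrace-class] objects, or a data.frame with columns
#'   `subject`, `session`, `mean_mm` (and optionally `sd_mm`) of
#'   already-summarized per-session amplitudes.
#' @return list(table = data.frame(subject, session, mean_mm, sd_mm),
#'   overallMean, overallSd) in mm.
#' @export
summarizeCohort <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("subject", "session", "mean_mm") %in% names(x)))
    tab <- x
    if (is.null(tab$sd_mm)) tab$sd_mm <- NA_real_
  } else {
    rows <- list()
    for (i in seq_along(x)) {
      for (k in seq_along(x[[i]])) {
        s <- summarizeDisplacement(x[[i]][[k]])
        rows[[length(rows) + 1L]] <- data.frame(
          subject = i, session = k, mean_mm = s$mean, sd_mm = s$sd)
      }
    }
    tab <- do.call(rbind, rows)
  }
  list(table = tab, overallMean = mean(tab$mean_mm),
       overallSd = stats::sd(tab$mean_mm))
}
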