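# Ground-truth extraction from binary liver segmentation masks: largest
# 8-connected component, hole filling and morphological closing, boundary
# extraction (4-connectivity), x-axis edge tracking inside an ROI, and
# segmentation quality metrics (Dice, Hausdorff, ROI-restricted Hausdorff).
#
# Pixel conventions: (row, col), 0-based, ROI ranges half-open. Increasing
# column = positive SI displacement (configurable sign).

.asMaskMatrix <- function(x) {
  m <- if (is(x, "BinaryMask")) x@mask else x
  storage.mode(m) <- "integer"
  m
}

#' Contrast-stretch and crop an ultrasound frame
#'
#' Percentile normalization (1st-99th by default) to [0, 1] followed by an
#' ROI crop, the pre-processing applied before a pluggable segmenter. A
#' constant image maps to all zeros (degenerate stretch guarded).
#'
#' @param image numeric matrix of intensities.
#' @param crop a [RoiBox-class] (half-open, 0-based); typically 512 x 512.
#' @param probs lower/upper stretch percentiles as fractions.
#' @return cropped matrix with values in [0, 1].
#' @export
preprocessImage <- function(image, crop, probs = c(0.01, 0.99)) {
  stopifnot(is.matrix(image), is(crop, "RoiBox"))
  if (crop@row1 > nrow(image) || crop@col1 > ncol(image))
    stop("crop box lies outside the image")
  out <- image[(crop@row0 + 1L):crop@row1, (crop@col0 + 1L):crop@col1,
               drop = FALSE]
  q <- stats::quantile(out, probs, names = FALSE)
  if (q[2L] == q[1L]) return(array(0, dim(out)))
  pmin(pmax((out - q[1L]) / (q[2L] - q[1L]), 0), 1)
}

#' Post-process a segmentation mask
#'
#' Keeps only the largest 8-connected foreground component (ties broken
#' toward the component whose first pixel comes earliest in row-major
#' order), fills interior holes, and applies binary closing with a disc
#' structuring element.
#'
#' @param mask a [BinaryMask-class] or 0/1 matrix.
#' @param closingRadius disc radius in px for the closing (0 disables;
#'   default 2).
#' @param frame frame id used in error messages.
#' @return same type as the input (BinaryMask in, BinaryMask out).
#' @export
postprocessMask <- function(mask, closingRadius = 2L, frame = NA_integer_) {
  m <- .asMaskMatrix(mask)
  if (sum(m) == 0L)
    stop("empty segmentation mask (frame ", frame, ")")
  lab <- .cpp_label8(m)
  sizes <- tabulate(lab[lab > 0L])
  # labels are issued in row-major discovery order, so the smallest label
  # among the largest components is the required tie-break
  keep <- which(sizes == max(sizes))[1L]
  m2 <- matrix(as.integer(lab == keep), nrow(m), ncol(m))
  m2 <- .fillHoles(m2)
  if (closingRadius > 0L) {
    brush <- EBImage::makeBrush(2L * as.integer(closingRadius) + 1L,
                                shape = "disc")
    m2 <- matrix(as.integer(EBImage::closing(m2, brush) > 0), nrow(m), ncol(m))
    m2 <- .fillHoles(m2)
  }
  if (is(mask, "BinaryMask"))
    BinaryMask(m2, pixelSpacing = mask@pixelSpacing, timestamp = mask@timestamp)
  else m2
}

# Fill interior holes: background components not connected to the image
# border (via EBImage::fillHull).
.fillHoles <- function(m) {
  matrix(as.integer(EBImage::fillHull(m) > 0), nrow(m), ncol(m))
}

#' Extract the boundary pixels of a mask
#'
#' A boundary pixel is a foreground pixel with at least one background
#' 4-neighbor; the image border counts as background.
#'
#' @param mask a [BinaryMask-class] or 0/1 matrix.
#' @return integer matrix with columns `row`, `col` (0-based), one row per
#'   edge pixel, ordered row-major.
#' @export
extractEdge <- function(mask) {
  m <- .asMaskMatrix(mask)
  if (sum(m) == 0L) stop("cannot extract edges of an empty mask")
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- m
  core <- pad[2:(nr + 1L), 2:(nc + 1L)]
  nbrMin <- pmin(pad[1:nr, 2:(nc + 1L)], pad[3:(nr + 2L), 2:(nc + 1L)],
                 pad[2:(nr + 1L), 1:nc], pad[2:(nr + 1L), 3:(nc + 2L)])
  edge <- core == 1L & nbrMin == 0L
  idx <- which(t(edge))  # row-major ordering
  cols <- (idx - 1L) %% nc
  rows <- (idx - 1L) %/% nc
  cbind(row = as.integer(rows), col = as.integer(cols))
}

.edgeInRoi <- function(edge, roi) {
  if (is.null(roi)) return(edge)
  keep <- edge[, "row"] >= roi@row0 & edge[, "row"] < roi@row1 &
    edge[, "col"] >= roi@col0 & edge[, "col"] < roi@col1
  edge[keep, , drop = FALSE]
}

#' Track liver displacement along the image x-axis
#'
#' For each frame the tracked coordinate is the mean (or median) column of
#' the edge pixels inside the ROI; displacement is
#' `(coordinate - coordinate of frame 1) * pixelSpacing` cm, reported in mm,
#' then optionally smoothed with a zero-phase (forward-backward)
#' second-order Butterworth low-pass. The default 1 Hz cutoff sits well
#' above the breathing band (0.1-0.5 Hz) and below pixel-quantization
#' chatter.
#'
#' @param edges list of edge-pixel matrices (see [extractEdge()]) or of
#'   [BinaryMask-class]/0-1 matrices (edges are then extracted per frame).
#' @param roi a [RoiBox-class] restricting tracking to the moving border.
#' @param pixelSpacing cm per pixel (default 0.027).
#' @param timestamps frame times in seconds; default frames at `rate`.
#' @param rate frame rate in Hz used when `timestamps` is NULL (default 15).
#' @param filter logical; apply the zero-phase low-pass (default TRUE).
#' @param cutoffHz low-pass cutoff (default 1).
#' @param filterOrder Butterworth order (default 2).
#' @param summary "mean" (default) or "median" edge column.
#' @param positiveSign +1 (default): increasing column is positive SI.
#' @param maxGap interpolate over at most this many consecutive frames with
#'   no edge pixel inside the ROI (default 0: such a frame is an error).
#' @return a [DisplacementTrace-class], SI channel in mm.
#' @export
trackDisplacement <- function(edges, roi, pixelSpacing = 0.027,
                              timestamps = NULL, rate = 15, filter = TRUE,
                              cutoffHz = 1, filterOrder = 2L,
                              summary = c("mean", "median"),
                              positiveSign = 1, maxGap = 0L) {
  summary <- match.arg(summary)
  stopifnot(is(roi, "RoiBox"))
  n <- length(edges)
  if (n == 0L) stop("no frames")
  if (is.null(timestamps)) timestamps <- (seq_len(n) - 1L) / rate
  coord <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    e <- edges[[i]]
    if (!is.matrix(e) || is.null(colnames(e)) || !all(c("row", "col") %in% colnames(e)))
      e <- extractEdge(e)
    e <- .edgeInRoi(e, roi)
    if (nrow(e) > 0L)
      coord[i] <- if (summary == "mean") mean(e[, "col"]) else
        stats::median(e[, "col"])
  }
  if (anyNA(coord)) {
    gaps <- rle(is.na(coord))
    if (is.na(coord[1L]) || is.na(coord[n]) ||
        max(gaps$lengths[gaps$values]) > maxGap) {
      bad <- which(is.na(coord))[1L]
      stop("no edge pixels inside the ROI at frame ", bad)
    }
    coord <- stats::approx(timestamps[!is.na(coord)], coord[!is.na(coord)],
                           xout = timestamps)$y
  }
  dispMm <- positiveSign * (coord - coord[1L]) * pixelSpacing * 10
  if (isTRUE(filter) && n > 6L * filterOrder) {
    fs <- 1 / stats::median(diff(timestamps))
    if (cutoffHz < fs / 2) {
      bw <- signal::butter(filterOrder, cutoffHz / (fs / 2), type = "low")
      dispMm <- as.numeric(signal::filtfilt(bw, dispMm))
    }
  }
  DisplacementTrace(timestamps, dispMm)
}

#' Dice overlap score, in percent
#'
#' `100 * 2|A intersect B| / (|A| + |B|)`; symmetric. Undefined (NA with a
#' warning) when both masks are empty.
#'
#' @param a,b [BinaryMask-class] or 0/1 matrices of equal shape.
#' @return Dice score in percent.
#' @export
dice <- function(a, b) {
  ma <- .asMaskMatrix(a); mb <- .asMaskMatrix(b)
  if (!all(dim(ma) == dim(mb))) stop("masks must have the same shape")
  denom <- sum(ma) + sum(mb)
  if (denom == 0L) {
    warning("both masks empty: Dice undefined")
    return(NA_real_)
  }
  100 * 2 * sum(ma & mb) / denom
}

#' Symmetric Hausdorff distance between edge sets
#'
#' `max(max_a min_b d, max_b min_a d)` in Euclidean pixel distance,
#' converted to mm with the isotropic pixel spacing (`px * spacing * 10`).
#' The ROI variant restricts BOTH sets to the box before computing.
#'
#' @param a,b edge matrices (see [extractEdge()]).
#' @param pixelSpacing cm per pixel (default 0.027).
#' @param roi optional [RoiBox-class].
#' @return distance in mm; the pixel value is attached as attribute `"px"`.
#' @export
hausdorff <- function(a, b, pixelSpacing = 0.027, roi = NULL) {
  if (!is.null(roi)) {
    a <- .edgeInRoi(a, roi)
    b <- .edgeInRoi(b, roi)
    if (nrow(a) == 0L) stop("first edge set is empty after ROI restriction")
    if (nrow(b) == 0L) stop("second edge set is empty after ROI restriction")
  }
  if (nrow(a) == 0L || nrow(b) == 0L) stop("edge sets must be non-empty")
  d2 <- outer(a[, "row"], b[, "row"], `-`)^2 +
    outer(a[, "col"], b[, "col"], `-`)^2
  hPx <- sqrt(max(max(apply(d2, 1L, min)), max(apply(d2, 2L, min))))
  out <- hPx * pixelSpacing * 10
  attr(out, "px") <- hPx
  out
}

#' Evaluate segmentation quality on sampled frames
#'
#' Draws `nSamples` frames without replacement (seeded) and reports Dice,
#' Hausdorff and ROI-restricted Hausdorff as mean +/- sd over the sample.
#' If fewer frames than `nSamples` exist, all frames are used and the
#' result carries a warning record.
#'
#' @param masks,references aligned lists of [BinaryMask-class] or 0/1
#'   matrices (predicted and reference).
#' @param nSamples frames to sample (default 20).
#' @param seed RNG seed for the sample.
#' @param roi optional [RoiBox-class] for the ROI-Hausdorff column.
#' @param pixelSpacing cm per pixel.
#' @return list(summary = data.frame(metric, mean, sd), perFrame =
#'   data.frame, frames = sampled indices, warnings = character()).
#' @export
evaluateSegmentation <- function(masks, references, nSamples = 20L, seed = 1L,
                                 roi = NULL, pixelSpacing = 0.027) {
  if (length(masks) != length(references))
    stop("'masks' and 'references' must be aligned")
  n <- length(masks)
  if (n == 0L) stop("no frames")
  warn <- character(0)
  if (n < nSamples) {
    warn <- sprintf("only %d frames available; using all instead of %d",
                    n, nSamples)
    idx <- seq_len(n)
  } else {
    idx <- sort(.withSeed(seed, sample.int(n, nSamples)))
  }
  perFrame <- do.call(rbind, lapply(idx, function(i) {
    ea <- extractEdge(masks[[i]])
    eb <- extractEdge(references[[i]])
    hd <- hausdorff(ea, eb, pixelSpacing)
    hdRoi <- if (is.null(roi)) NA_real_ else
      as.numeric(hausdorff(ea, eb, pixelSpacing, roi = roi))
    data.frame(frame = i, dice = dice(masks[[i]], references[[i]]),
               hausdorffMm = as.numeric(hd), hausdorffPx = attr(hd, "px"),
               hausdorffRoiMm = hdRoi)
  }))
  msd <- function(v) c(mean = mean(v), sd = if (length(v) > 1L) stats::sd(v) else NA_real_)
  summary <- data.frame(
    metric = c("dice_pct", "hausdorff_mm", "hausdorff_px", "hausdorff_roi_mm"),
    rbind(msd(perFrame$dice), msd(perFrame$hausdorffMm),
          msd(perFrame$hausdorffPx), msd(perFrame$hausdorffRoiMm)))
  if (length(warn)) warning(warn)
  list(summary = summary, perFrame = perFrame, frames = idx, warnings = warn)
}

#' Per-cycle peak-to-trough amplitude summary
#'
#' Detects breathing cycles by prominence-based peak/trough detection and
#' reports the mean +/- sd of per-cycle amplitudes (each peak paired with
#' the preceding trough), in mm.
#'
#' @param trace a [DisplacementTrace-class] (or numeric vector, mm).
#' @param minProminenceFrac minimum peak prominence as a fraction of the
#'   global range (default 0.25).
#' @return list(mean, sd, amplitudes).
#' @export
summarizeDisplacement <- function(trace, minProminenceFrac = 0.25) {
  v <- if (is(trace, "DisplacementTrace")) siValues(trace) else as.numeric(trace)
  rng <- max(v) - min(v)
  if (rng == 0) stop("no detectable breathing cycles (constant trace)")
  prom <- minProminenceFrac * rng
  pk <- pracma::findpeaks(v, minpeakdistance = 2L, zero = "+")
  tr <- pracma::findpeaks(-v, minpeakdistance = 2L, zero = "+")
  ext <- rbind(
    if (!is.null(pk)) data.frame(idx = pk[, 2L], val = pk[, 1L], type = "peak"),
    if (!is.null(tr)) data.frame(idx = tr[, 2L], val = -tr[, 1L], type = "trough"))
  if (is.null(ext) || nrow(ext) == 0L) stop("no detectable breathing cycles")
  ext <- ext[order(ext$idx), ]
  # enforce alternation: within a run of the same type keep the extreme one
  keep <- logical(nrow(ext))
  i <- 1L
  while (i <= nrow(ext)) {
    j <- i
    while (j < nrow(ext) && ext$type[j + 1L] == ext$type[i]) j <- j + 1L
    run <- i:j
    sel <- if (ext$type[i] == "peak") run[which.max(ext$val[run])]
           else run[which.min(ext$val[run])]
    keep[sel] <- TRUE
    i <- j + 1L
  }
  ext <- ext[keep, ]
  amps <- numeric(0)
  for (k in seq_len(nrow(ext))) {
    if (ext$type[k] == "peak" && k > 1L && ext$type[k - 1L] == "trough") {
      a <- ext$val[k] - ext$val[k - 1L]
      if (a >= prom) amps <- c(amps, a)
    }
  }
  if (length(amps) == 0L) stop("no detectable breathing cycles")
  list(mean = mean(amps),
       sd = if (length(amps) > 1L) stats::sd(amps) else 0,
       amplitudes = amps)
}
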