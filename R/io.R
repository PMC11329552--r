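# On-disk formats: ASCII PLY point clouds with a frames.csv manifest,
# displacement and surrogate CSVs, 8-bit PNG mask sequences, JSON dataset
# manifests and model reports. Point clouds are stored in meters; traces
# and surrogates in mm.

#' Write a point cloud as ASCII PLY
#'
#' Vertex-only PLY (x, y, z float properties, meters).
#'
#' @param cloud a [TimedPointCloud-class] or N x 3 matrix.
#' @param path output file.
#' @export
writePly <- function(cloud, path) {
  p <- .asPointMatrix(cloud)
  header <- c("ply", "format ascii 1.0",
              paste("element vertex", nrow(p)),
              "property float x", "property float y", "property float z",
              "end_header")
  body <- sprintf("%.9g %.9g %.9g", p[, 1L], p[, 2L], p[, 3L])
  writeLines(c(header, body), path)
}

#' Read an ASCII PLY point cloud
#'
#' @param path PLY file with x/y/z vertex properties.
#' @param timestamp,frameId metadata for the returned cloud.
#' @return a [TimedPointCloud-class].
#' @export
readPly <- function(path, timestamp = 0, frameId = 0L) {
  lines <- readLines(path)
  if (length(lines) < 2L || trimws(lines[1L]) != "ply")
    stop("not a PLY file: ", path)
  endHdr <- which(trimws(lines) == "end_header")[1L]
  if (is.na(endHdr)) stop("malformed PLY header: ", path)
  nVertex <- NA_integer_
  for (l in lines[seq_len(endHdr)]) {
    tok <- strsplit(trimws(l), "\\s+")[[1L]]
    if (length(tok) == 3L && tok[1L] == "element" && tok[2L] == "vertex")
      nVertex <- as.integer(tok[3L])
    if (length(tok) >= 2L && tok[1L] == "format" && tok[2L] != "ascii")
      stop("only ASCII PLY is supported: ", path)
  }
  if (is.na(nVertex)) stop("no vertex element in PLY header: ", path)
  body <- lines[(endHdr + 1L):(endHdr + nVertex)]
  vals <- utils::read.table(text = body, col.names = c("x", "y", "z"))
  TimedPointCloud(as.matrix(vals), timestamp = timestamp, frameId = frameId)
}

#' Write a point-cloud sequence (PLY frames + manifest)
#'
#' One `frame_<id>.ply` per cloud and a `frames.csv` manifest with columns
#' frame_id, timestamp_s, path.
#'
#' @param sequence list of [TimedPointCloud-class].
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
writeCloudSequence <- function(sequence, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- do.call(rbind, lapply(sequence, function(cl) {
    fn <- sprintf("frame_%06d.ply", cl@frameId)
    writePly(cl, file.path(dir, fn))
    data.frame(frame_id = cl@frameId, timestamp_s = cl@timestamp, path = fn)
  }))
  manPath <- file.path(dir, "frames.csv")
  utils::write.csv(man, manPath, row.names = FALSE)
  invisible(manPath)
}

#' Read a point-cloud sequence from a frames.csv manifest
#'
#' @param dir directory holding `frames.csv` and the PLY frames.
#' @return list of [TimedPointCloud-class], in manifest order.
#' @export
readCloudSequence <- function(dir) {
  man <- utils::read.csv(file.path(dir, "frames.csv"))
  lapply(seq_len(nrow(man)), function(i)
    readPly(file.path(dir, man$path[i]), timestamp = man$timestamp_s[i],
            frameId = man$frame_id[i]))
}

#' Write a displacement trace as CSV
#'
#' Columns timestamp_s, si_mm and (when present) ap_mm.
#'
#' @param trace a [DisplacementTrace-class].
#' @param path output CSV.
#' @export
writeTraceCsv <- function(trace, path) {
  df <- data.frame(timestamp_s = timestamps(trace), si_mm = siValues(trace))
  if (length(apValues(trace))) df$ap_mm <- apValues(trace)
  utils::write.csv(df, path, row.names = FALSE)
}

#' Read a displacement trace CSV
#'
#' @param path CSV with columns timestamp_s, si_mm and optionally ap_mm.
#' @return a [DisplacementTrace-class].
#' @export
readTraceCsv <- function(path) {
  df <- utils::read.csv(path)
  DisplacementTrace(df$timestamp_s, df$si_mm,
                    if (!is.null(df$ap_mm)) df$ap_mm else numeric(0))
}

#' Write a surrogate series as CSV plus JSON sidecar
#'
#' The CSV holds timestamp_s and surrogate_mm; the sidecar
#' (`<path>.json`) records the reference frame and the distance convention.
#'
#' @param series a [SurrogateSeries-class].
#' @param path output CSV.
#' @export
writeSurrogateCsv <- function(series, path) {
  utils::write.csv(data.frame(timestamp_s = timestamps(series),
                              surrogate_mm = surrogateValues(series)),
                   path, row.names = FALSE)
  jsonlite::write_json(
    list(reference_frame_id = series@referenceFrameId,
         signed = series@signed,
         convention = if (series@signed) "signed-height-axis"
                      else "unsigned-nearest-neighbor"),
    paste0(path, ".json"), auto_unbox = TRUE)
}

#' Read a surrogate series CSV (with optional JSON sidecar)
#'
#' @param path CSV written by [writeSurrogateCsv()].
#' @return a [SurrogateSeries-class].
#' @export
readSurrogateCsv <- function(path) {
  df <- utils::read.csv(path)
  side <- paste0(path, ".json")
  refId <- NA_integer_; signed <- FALSE
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side)
    refId <- as.integer(meta$reference_frame_id)
    signed <- isTRUE(meta$signed)
  }
  SurrogateSeries(df$timestamp_s, df$surrogate_mm, refId, signed)
}

#' Write a binary-mask sequence as 8-bit PNGs plus manifest
#'
#' Foreground is stored as 255, background as 0, with a `frames.csv`
#' manifest (frame_id, timestamp_s, path) and the pixel spacing in
#' `masks.json`.
#'
#' @param masks list of [BinaryMask-class].
#' @param dir output directory.
#' @return the manifest path, invisibly.
#' @export
writeMaskSequence <- function(masks, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- do.call(rbind, lapply(seq_along(masks), function(i) {
    m <- masks[[i]]
    fn <- sprintf("mask_%06d.png", i - 1L)
    png::writePNG(maskMatrix(m) * 1.0, file.path(dir, fn))
    data.frame(frame_id = i - 1L, timestamp_s = m@timestamp, path = fn)
  }))
  manPath <- file.path(dir, "frames.csv")
  utils::write.csv(man, manPath, row.names = FALSE)
  jsonlite::write_json(list(pixel_spacing_cm = masks[[1L]]@pixelSpacing),
                       file.path(dir, "masks.json"), auto_unbox = TRUE)
  invisible(manPath)
}

#' Read a binary-mask sequence written by [writeMaskSequence()]
#'
#' Any pixel above 0.5 counts as foreground.
#'
#' @param dir directory holding `frames.csv`, `masks.json` and the PNGs.
#' @return list of [BinaryMask-class].
#' @export
readMaskSequence <- function(dir) {
  man <- utils::read.csv(file.path(dir, "frames.csv"))
  spacing <- 0.027
  metaPath <- file.path(dir, "masks.json")
  if (file.exists(metaPath))
    spacing <- as.numeric(jsonlite::read_json(metaPath)$pixel_spacing_cm)
  lapply(seq_len(nrow(man)), function(i) {
    img <- png::readPNG(file.path(dir, man$path[i]))
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    BinaryMask(matrix(as.integer(img > 0.5), nrow(img), ncol(img)),
               pixelSpacing = spacing, timestamp = man$timestamp_s[i])
  })
}

#' Write paired session data as CSV
#'
#' Columns timestamp_s, surrogate_mm, displacement_mm, session_id, hold.
#'
#' @param sessions a [SessionData-class] or list of them.
#' @param path output CSV.
#' @export
writeSessionCsv <- function(sessions, path) {
  if (is(sessions, "SessionData")) sessions <- list(sessions)
  df <- do.call(rbind, lapply(sessions, function(s)
    data.frame(timestamp_s = timestamps(s), surrogate_mm = surrogateValues(s),
               displacement_mm = siValues(s), session_id = sessionId(s),
               hold = holdFlags(s))))
  utils::write.csv(df, path, row.names = FALSE)
}

#' Read paired session data CSV
#'
#' @param path CSV written by [writeSessionCsv()].
#' @return list of [SessionData-class], one per session_id.
#' @export
readSessionCsv <- function(path) {
  df <- utils::read.csv(path)
  lapply(split(df, df$session_id), function(d)
    SessionData(d$session_id[1L], d$timestamp_s, d$surrogate_mm,
                d$displacement_mm,
                if (!is.null(d$hold)) d$hold else rep(FALSE, nrow(d))))
}

#' Write a simulated dataset to disk
#'
#' Lays out one directory per session (trace CSV, cloud PLY sequence and
#' mask PNG sequence when present) plus a `dataset.json` manifest recording
#' the generation parameters.
#'
#' @param sessionSet output of [simulateSessionSet()].
#' @param dir output directory.
#' @param params,protocol the generation parameters, stored in the manifest.
#' @return `dir`, invisibly.
#' @export
writeDataset <- function(sessionSet, dir, params = NULL, protocol = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sessions <- lapply(sessionSet, function(sess) {
    sdir <- file.path(dir, sprintf("session_%02d", sess$sessionId))
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    writeTraceCsv(sess$trace, file.path(sdir, "trace.csv"))
    if (!is.null(sess$clouds))
      writeCloudSequence(sess$clouds, file.path(sdir, "clouds"))
    if (!is.null(sess$masks))
      writeMaskSequence(sess$masks, file.path(sdir, "masks"))
    entry <- list(session_id = sess$sessionId,
                  trace = file.path(basename(sdir), "trace.csv"))
    if (!is.null(sess$clouds))
      entry$clouds <- file.path(basename(sdir), "clouds")
    if (!is.null(sess$masks))
      entry$masks <- file.path(basename(sdir), "masks")
    entry$hold_windows <- sess$holdWindows
    entry
  })
  manifest <- list(sessions = sessions)
  if (!is.null(params))
    manifest$breathing <- list(
      amplitude_si_mm = params@amplitudeSi, amplitude_ap_mm = params@amplitudeAp,
      frequency_hz = params@frequency, waveform = params@waveform,
      noise_sd_mm = params@noiseSd, seed = params@seed)
  if (!is.null(protocol))
    manifest$protocol <- list(
      session_duration_s = protocol@sessionDuration,
      n_sessions = protocol@nSessions,
      breathhold_duration_s = protocol@breathholdDuration,
      surrogate_rate_hz = protocol@surrogateRate,
      groundtruth_rate_hz = protocol@groundtruthRate)
  jsonlite::write_json(manifest, file.path(dir, "dataset.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a dataset written by [writeDataset()]
#'
#' @param dir dataset directory.
#' @param clouds,masks logical; load the heavy sequences (default TRUE
#'   when present on disk).
#' @return list of per-session lists (sessionId, trace, clouds, masks,
#'   holdWindows), plus the manifest as attribute `"manifest"`.
#' @export
readDataset <- function(dir, clouds = TRUE, masks = TRUE) {
  manifest <- jsonlite::read_json(file.path(dir, "dataset.json"),
                                  simplifyVector = FALSE)
  out <- lapply(manifest$sessions, function(sess) {
    cl <- NULL
    mk <- NULL
    if (isTRUE(clouds) && is.character(sess$clouds) && length(sess$clouds) == 1L)
      cl <- readCloudSequence(file.path(dir, sess$clouds))
    if (isTRUE(masks) && is.character(sess$masks) && length(sess$masks) == 1L)
      mk <- readMaskSequence(file.path(dir, sess$masks))
    hw <- sess$hold_windows
    holdWindows <- if (length(hw))
      data.frame(start = vapply(hw, function(h) as.numeric(h$start), numeric(1)),
                 end = vapply(hw, function(h) as.numeric(h$end), numeric(1)))
    else data.frame(start = numeric(0), end = numeric(0))
    list(sessionId = as.integer(sess$session_id),
         trace = readTraceCsv(file.path(dir, sess$trace)),
         clouds = cl, masks = mk, holdWindows = holdWindows)
  })
  attr(out, "manifest") <- manifest
  out
}

#' Write a model report as JSON and CSV
#'
#' The CSV is the regime x partition x metric table of [reportTable()];
#' the JSON additionally carries the per-session breakdown.
#'
#' @param reports a [ModelReport-class] or list of them.
#' @param stem output path stem; writes `<stem>.csv` and `<stem>.json`.
#' @export
writeReport <- function(reports, stem) {
  if (is(reports, "ModelReport")) reports <- list(reports)
  tab <- do.call(rbind, lapply(reports, reportTable))
  utils::write.csv(tab, paste0(stem, ".csv"), row.names = FALSE)
  jsonlite::write_json(lapply(reports, function(r)
    list(regime = r@regime, degree = r@degree,
         train = as.list(r@train), test = as.list(r@test),
         per_session = r@perSession)),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
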