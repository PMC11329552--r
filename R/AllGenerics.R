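# Accessor generics. Slot access from user code goes through these.

#' @rdname timestamps
#' @export
setGeneric("timestamps", function(x) standardGeneric("timestamps"))

#' @rdname frameId
#' @export
setGeneric("frameId", function(x) standardGeneric("frameId"))

#' @rdname cloudPoints
#' @export
setGeneric("cloudPoints", function(x) standardGeneric("cloudPoints"))

#' @rdname nPoints
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))

#' @rdname surrogateValues
#' @export
setGeneric("surrogateValues", function(x) standardGeneric("surrogateValues"))

#' @rdname siValues
#' @export
setGeneric("siValues", function(x) standardGeneric("siValues"))

#' @rdname apValues
#' @export
setGeneric("apValues", function(x) standardGeneric("apValues"))

#' @rdname modelDegree
#' @export
setGeneric("modelDegree", function(x) standardGeneric("modelDegree"))

#' @rdname sessionId
#' @export
setGeneric("sessionId", function(x) standardGeneric("sessionId"))

#' @rdname holdFlags
#' @export
setGeneric("holdFlags", function(x) standardGeneric("holdFlags"))

#' @rdname maskMatrix
#' @export
setGeneric("maskMatrix", function(x) standardGeneric("maskMatrix"))

#' @rdname pixelSpacing
#' @export
setGeneric("pixelSpacing", function(x) standardGeneric("pixelSpacing"))

#' @rdname reportTable
#' @export
setGeneric("reportTable", function(x, ...) standardGeneric("reportTable"))

# ---------------------------------------------------------------------------

#' Timestamps of a timed object
#'
#' @param x a rimest object carrying a time axis.
#' @return numeric vector of seconds.
#' @name timestamps
NULL

#' @rdname timestamps
setMethod("timestamps", "TimedPointCloud", function(x) x@timestamp)
#' @rdname timestamps
setMethod("timestamps", "SurrogateSeries", function(x) x@timestamps)
#' @rdname timestamps
setMethod("timestamps", "DisplacementTrace", function(x) x@timestamps)
#' @rdname timestamps
setMethod("timestamps", "SessionData", function(x) x@timestamps)

#' Frame identifier
#'
#' @param x a [TimedPointCloud-class] or [SurrogateSeries-class].
#' @return integer frame id (for a series: the reference frame id).
#' @name frameId
NULL

#' @rdname frameId
setMethod("frameId", "TimedPointCloud", function(x) x@frameId)
#' @rdname frameId
setMethod("frameId", "SurrogateSeries", function(x) x@referenceFrameId)

#' Point coordinates of a cloud
#'
#' @param x a [TimedPointCloud-class].
#' @return N x 3 numeric matrix, meters.
#' @name cloudPoints
NULL

#' @rdname cloudPoints
setMethod("cloudPoints", "TimedPointCloud", function(x) x@points)

#' Number of points in a cloud
#'
#' @param x a [TimedPointCloud-class].
#' @return integer point count.
#' @name nPoints
NULL

#' @rdname nPoints
setMethod("nPoints", "TimedPointCloud", function(x) nrow(x@points))

#' Surrogate values of a series or session
#'
#' @param x a [SurrogateSeries-class] or [SessionData-class].
#' @return numeric vector in mm.
#' @name surrogateValues
NULL

#' @rdname surrogateValues
setMethod("surrogateValues", "SurrogateSeries", function(x) x@values)
#' @rdname surrogateValues
setMethod("surrogateValues", "SessionData", function(x) x@x)

#' Superior-inferior displacement channel
#'
#' @param x a [DisplacementTrace-class] or [SessionData-class].
#' @return numeric vector in mm (for SessionData: the ground-truth y).
#' @name siValues
NULL

#' @rdname siValues
setMethod("siValues", "DisplacementTrace", function(x) x@si)
#' @rdname siValues
setMethod("siValues", "SessionData", function(x) x@y)

#' Anterior-posterior displacement channel
#'
#' @param x a [DisplacementTrace-class].
#' @return numeric vector in mm (length 0 if the trace has no AP channel).
#' @name apValues
NULL

#' @rdname apValues
setMethod("apValues", "DisplacementTrace", function(x) x@ap)

#' Degree of a polynomial model
#'
#' @param x a [PolynomialModel-class].
#' @return integer degree.
#' @name modelDegree
NULL

#' @rdname modelDegree
setMethod("modelDegree", "PolynomialModel", function(x) x@degree)

#' @describeIn modelDegree coefficients beta (intercept first), original
#'   surrogate scale.
#' @exportMethod coef
setMethod("coef", "PolynomialModel", function(object, ...) object@coefficients)

#' Session identifier
#'
#' @param x a [SessionData-class].
#' @return integer session id.
#' @name sessionId
NULL

#' @rdname sessionId
setMethod("sessionId", "SessionData", function(x) x@sessionId)

#' Breath-hold flags of a session
#'
#' @param x a [SessionData-class].
#' @return logical vector, TRUE inside detected holds.
#' @name holdFlags
NULL

#' @rdname holdFlags
setMethod("holdFlags", "SessionData", function(x) x@hold)

#' Pixel matrix of a binary mask
#'
#' @param x a [BinaryMask-class].
#' @return integer 0/1 matrix.
#' @name maskMatrix
NULL

#' @rdname maskMatrix
setMethod("maskMatrix", "BinaryMask", function(x) x@mask)

#' Pixel spacing of a mask
#'
#' @param x a [BinaryMask-class].
#' @return cm per pixel.
#' @name pixelSpacing
NULL

#' @rdname pixelSpacing
setMethod("pixelSpacing", "BinaryMask", function(x) x@pixelSpacing)

#' Tabular view of a model report
#'
#' @param x a [ModelReport-class].
#' @param ... unused.
#' @return data.frame with one row per regime x partition x metric,
#'   columns regime, partition, metric, mean, sd.
#' @name reportTable
NULL

#' @rdname reportTable
setMethod("reportTable", "ModelReport", function(x, ...) {
  data.frame(
    regime = x@regime,
    partition = rep(c("train", "test"), each = 2L),
    metric = rep(c("MAE_mm", "R2_pct"), 2L),
    mean = c(x@train[["mae"]], x@train[["r2"]], x@test[["mae"]], x@test[["r2"]]),
    sd = c(x@train[["maeSd"]], x@train[["r2Sd"]], x@test[["maeSd"]], x@test[["r2Sd"]]),
    stringsAsFactors = FALSE)
})

# ---------------------------------------------------------------------------
# show() methods
# ---------------------------------------------------------------------------

setMethod("show", "TimedPointCloud", function(object) {
  cat(sprintf("%s: %d points, t = %.3f s, frame %d\n", class(object),
              nrow(object@points), object@timestamp, object@frameId))
})

setMethod("show", "SurrogateSeries", function(object) {
  n <- length(object@values)
  cat(sprintf("SurrogateSeries: %d samples, %s convention, reference frame %s\n",
              n, if (object@signed) "signed" else "unsigned",
              object@referenceFrameId))
  if (n > 0L)
    cat(sprintf("  range %.2f .. %.2f mm over %.2f .. %.2f s\n",
                min(object@values), max(object@values),
                object@timestamps[1L], object@timestamps[n]))
})

setMethod("show", "DisplacementTrace", function(object) {
  n <- length(object@timestamps)
  cat(sprintf("DisplacementTrace: %d samples%s\n", n,
              if (length(object@ap)) ", SI + AP channels" else ", SI channel"))
  if (n > 0L)
    cat(sprintf("  SI range %.2f .. %.2f mm over %.2f .. %.2f s\n",
                min(object@si), max(object@si),
                object@timestamps[1L], object@timestamps[n]))
})

setMethod("show", "PolynomialModel", function(object) {
  cat(sprintf("PolynomialModel: degree %d\n  beta = (%s)\n", object@degree,
              paste(sprintf("%.4g", object@coefficients), collapse = ", ")))
  if (!is.null(object@meta$regime))
    cat(sprintf("  regime: %s\n", object@meta$regime))
})

setMethod("show", "SessionData", function(object) {
  cat(sprintf("SessionData S%d: %d samples (%d flagged as breath-hold)\n",
              object@sessionId, length(object@x), sum(object@hold)))
})

setMethod("show", "BinaryMask", function(object) {
  cat(sprintf("BinaryMask: %d x %d px, %d foreground, %.3f cm/px, t = %.3f s\n",
              nrow(object@mask), ncol(object@mask), sum(object@mask),
              object@pixelSpacing, object@timestamp))
})

setMethod("show", "ModelReport", function(object) {
  cat(sprintf("ModelReport (%s regime, degree %d)\n", object@regime, object@degree))
  fmt <- function(v) {
    if (is.na(v[["maeSd"]]))
      sprintf("MAE %.2f mm, R2 %.1f%%", v[["mae"]], v[["r2"]])
    else
      sprintf("MAE %.2f +/- %.2f mm, R2 %.1f +/- %.1f%%",
              v[["mae"]], v[["maeSd"]], v[["r2"]], v[["r2Sd"]])
  }
  cat("  train:", fmt(object@train), "\n")
  cat("  test: ", fmt(object@test), "\n")
})

setMethod("show", "StreamPair", function(object) {
  cat(sprintf("StreamPair: surrogate %d samples, ground truth %d samples, offset %s\n",
              length(object@surrogate@values), length(object@groundTruth@timestamps),
              if (is.na(object@offset)) "not yet estimated"
              else sprintf("%.3f s", object@offset)))
})
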