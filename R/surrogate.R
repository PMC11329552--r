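# Scalar surrogate from surface point clouds: mean distance from each point
# of the current cloud to its closest point in a maximum-inhalation
# reference cloud (directed, current -> reference). Units: clouds are in
# meters, the surrogate is reported in mm.

.asPointMatrix <- function(cloud) {
  if (is(cloud, "TimedPointCloud")) cloud@points
  else as.matrix(cloud)
}

#' Select the reference cloud of a sequence
#'
#' The default "extreme-height" strategy returns the frame whose mean
#' coordinate along the height axis is extremal in the inhalation direction
#' — the maximum-inhalation frame for a camera watching the rising abdomen.
#' Height axis and inhalation sign are configuration, never inferred. Ties
#' are broken toward the earliest frame.
#'
#' @param sequence non-empty list of [TimedPointCloud-class].
#' @param strategy "extreme-height" (default) or "index".
#' @param heightAxis coordinate axis of surface height (1, 2 or 3).
#' @param inhalationSign +1 if inhalation increases the height coordinate,
#'   -1 if it decreases it (camera above a supine subject).
#' @param index frame position (1-based within `sequence`) for the "index"
#'   strategy.
#' @return a [ReferenceCloud-class].
#' @export
selectReferenceCloud <- function(sequence,
                                 strategy = c("extreme-height", "index"),
                                 heightAxis = 3L, inhalationSign = 1,
                                 index = NULL) {
  strategy <- match.arg(strategy)
  if (length(sequence) == 0L) stop("'sequence' must be non-empty")
  if (strategy == "index") {
    if (is.null(index) || index < 1L || index > length(sequence))
      stop("'index' must point inside the sequence")
    return(ReferenceCloud(sequence[[index]], strategy = "index"))
  }
  h <- vapply(sequence, function(cl)
    inhalationSign * mean(.asPointMatrix(cl)[, heightAxis]), numeric(1))
  best <- which(h == max(h))[1L]   # earliest frame on ties
  ReferenceCloud(sequence[[best]], strategy = "extreme-height")
}

#' Compute the scalar surrogate of one frame
#'
#' Mean Euclidean distance from each point of `cloud` to its nearest
#' neighbor in `reference`, in mm. The directed (current -> reference)
#' unsigned convention is the default; `signed = TRUE` instead averages the
#' height-axis difference to the nearest reference point, oriented by
#' `inhalationSign`, for sensitivity analyses.
#'
#' @param cloud a [TimedPointCloud-class] (or N x 3 matrix, meters).
#' @param reference a [ReferenceCloud-class], [TimedPointCloud-class] or
#'   N x 3 matrix (meters).
#' @param signed use the signed height-axis convention.
#' @param heightAxis,inhalationSign height-axis configuration (signed
#'   convention only).
#' @return surrogate value in mm.
#' @examples
#' ref <- matrix(c(0, 0, 0, 1, 0, 0), ncol = 3, byrow = TRUE)
#' qu  <- matrix(c(0, 0, 1, 1, 0, 2), ncol = 3, byrow = TRUE)
#' computeSurrogate(rbind(qu, qu[1, ]), rbind(ref, ref[1, ]))  # 4000/3 mm
#' @export
computeSurrogate <- function(cloud, reference, signed = FALSE,
                             heightAxis = 3L, inhalationSign = 1) {
  q <- .asPointMatrix(cloud)
  r <- .asPointMatrix(reference)
  if (nrow(q) == 0L || nrow(r) == 0L) stop("clouds must be non-empty")
  tree <- .cpp_kdtree_build(r)
  nn <- .cpp_kdtree_nn(tree, q)
  if (signed)
    1000 * mean(inhalationSign * (r[nn$index, heightAxis] - q[, heightAxis]))
  else
    1000 * mean(nn$dist)
}

#' Compute the surrogate series of a frame sequence
#'
#' Applies [computeSurrogate()] to every frame against one reference cloud.
#' The spatial index over the reference is built once and reused across
#' frames; output timestamps are copied from the input sequence.
#'
#' @param sequence non-empty list of [TimedPointCloud-class].
#' @param reference the reference cloud (see [selectReferenceCloud()]).
#' @param signed,heightAxis,inhalationSign see [computeSurrogate()].
#' @return a [SurrogateSeries-class] (values in mm).
#' @export
computeSurrogateSeries <- function(sequence, reference, signed = FALSE,
                                   heightAxis = 3L, inhalationSign = 1) {
  if (length(sequence) == 0L) stop("'sequence' must be non-empty")
  r <- .asPointMatrix(reference)
  tree <- .cpp_kdtree_build(r)
  vals <- vapply(seq_along(sequence), function(i) {
    cl <- sequence[[i]]
    q <- .asPointMatrix(cl)
    if (nrow(q) == 0L)
      stop("empty cloud at frame ", if (is(cl, "TimedPointCloud")) cl@frameId else i)
    nn <- .cpp_kdtree_nn(tree, q)
    if (signed)
      1000 * mean(inhalationSign * (r[nn$index, heightAxis] - q[, heightAxis]))
    else
      1000 * mean(nn$dist)
  }, numeric(1))
  tt <- vapply(sequence, function(cl)
    if (is(cl, "TimedPointCloud")) cl@timestamp else NA_real_, numeric(1))
  refId <- if (is(reference, "TimedPointCloud")) reference@frameId else NA_integer_
  SurrogateSeries(tt, vals, referenceFrameId = refId, signed = signed)
}
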