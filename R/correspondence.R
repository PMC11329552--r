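# Polynomial OLS correspondence models between the surrogate x and the
# internal displacement y, and the three clinical training regimes:
#   single   — fit on all of session 1, test on each remaining session;
#   specific — fit on 70% of one session, test on its held-out 30%;
#   combined — pool the 70% train parts of all sessions, fit once, test on
#              each session's held-out 30%.

#' Fit a polynomial correspondence model by ordinary least squares
#'
#' Minimizes the sum of squared residuals of
#' y = beta0 + beta1 x + ... + betan x^n on a Vandermonde design. For
#' numerical stability x is centered and scaled before powers are formed
#' (QR solve); the returned coefficients are mapped back to the original
#' surrogate scale exactly.
#'
#' @param x surrogate values, mm.
#' @param y displacement values, mm.
#' @param degree polynomial degree n (default 3; the correspondence between
#'   abdominal surface displacement and liver motion is near-linear, and a
#'   low-order polynomial absorbs mild hysteresis-free curvature).
#' @param meta optional list of training metadata stored with the model.
#' @return a [PolynomialModel-class].
#' @examples
#' m <- fitPolynomial(c(0, 1, 2), c(0, 1, 4), degree = 2)
#' coef(m)  # (0, 0, 1): the data lie on y = x^2
#' @export
fitPolynomial <- function(x, y, degree = 3L, meta = list()) {
  degree <- as.integer(degree)
  if (degree < 0L) stop("'degree' must be >= 0")
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("'x' and 'y' must be finite")
  if (length(x) < degree + 1L)
    stop("need at least degree + 1 = ", degree + 1L, " samples")
  mu <- mean(x)
  sc <- stats::sd(x)
  if (!is.finite(sc) || sc == 0) sc <- 1
  z <- (x - mu) / sc
  design <- outer(z, 0:degree, `^`)
  qrd <- qr(design)
  if (qrd$rank < degree + 1L)
    stop("degenerate fit: fewer than ", degree + 1L,
         " distinct surrogate values for degree ", degree)
  gamma <- qr.coef(qrd, y)
  # expand sum_k gamma_k ((x - mu)/sc)^k into raw powers of x
  beta <- numeric(degree + 1L)
  for (k in 0:degree) {
    gk <- gamma[k + 1L] / sc^k
    for (j in 0:k)
      beta[j + 1L] <- beta[j + 1L] + gk * choose(k, j) * (-mu)^(k - j)
  }
  .PolynomialModel(degree = degree, coefficients = beta, meta = meta)
}

#' Predict displacement from surrogate values
#'
#' Evaluates the fitted polynomial by Horner's scheme.
#'
#' @param object a [PolynomialModel-class].
#' @param x surrogate values, mm.
#' @return estimated displacement, mm.
#' @exportMethod predict
setMethod("predict", "PolynomialModel", function(object, x, ...) {
  if (!all(is.finite(x))) stop("'x' must be finite")
  b <- object@coefficients
  out <- rep(b[length(b)], length(x))
  if (length(b) > 1L)
    for (k in seq(length(b) - 1L, 1L))
      out <- out * x + b[k]
  out
})

#' Mean absolute error
#'
#' @param y ground truth, mm.
#' @param yHat predictions, mm.
#' @return MAE in mm.
#' @export
mae <- function(y, yHat) {
  if (length(y) == 0L || length(y) != length(yHat))
    stop("'y' and 'yHat' must have equal non-zero length")
  mean(abs(y - yHat))
}

#' Coefficient of determination, in percent
#'
#' R^2 = 100 (1 - SSres / SStot). Negative values (a fit worse than the
#' mean, common for out-of-session tests) are reported as-is. If y has zero
#' variance, R^2 is undefined and NA is returned with a warning.
#'
#' @param y ground truth, mm.
#' @param yHat predictions, mm.
#' @return R^2 in percent, possibly negative; NA for zero-variance y.
#' @export
rSquared <- function(y, yHat) {
  if (length(y) == 0L || length(y) != length(yHat))
    stop("'y' and 'yHat' must have equal non-zero length")
  ssTot <- sum((y - mean(y))^2)
  if (ssTot == 0) {
    warning("zero-variance ground truth: R^2 undefined")
    return(NA_real_)
  }
  100 * (1 - sum((y - yHat)^2) / ssTot)
}

#' Split one session into train and test parts
#'
#' Default: chronologically contiguous split — the first
#' `floor(trainFraction n)` samples train, the rest test — which respects
#' the serial correlation of breathing data. A seeded random split is
#' available behind `mode = "random"`.
#'
#' @param session a [SessionData-class].
#' @param trainFraction fraction of samples used for training (default 0.7).
#' @param mode "chronological" (default) or "random".
#' @param seed mandatory integer seed for the random mode.
#' @param minSamples minimum samples each part must keep (default 2).
#' @return list(train = SessionData, test = SessionData).
#' @export
splitSession <- function(session, trainFraction = 0.7,
                         mode = c("chronological", "random"), seed = NULL,
                         minSamples = 2L) {
  mode <- match.arg(mode)
  stopifnot(is(session, "SessionData"))
  n <- length(session@x)
  nTrain <- floor(trainFraction * n)
  if (nTrain < minSamples || n - nTrain < minSamples)
    stop("session too short for a ", trainFraction, " split with parts of >= ",
         minSamples, " samples")
  if (mode == "chronological") {
    trainIdx <- seq_len(nTrain)
  } else {
    if (is.null(seed)) stop("random split requires an explicit 'seed'")
    trainIdx <- sort(.withSeed(seed, sample.int(n, nTrain)))
  }
  testIdx <- setdiff(seq_len(n), trainIdx)
  take <- function(i) SessionData(session@sessionId, session@timestamps[i],
                                  session@x[i], session@y[i], session@hold[i])
  list(train = take(trainIdx), test = take(testIdx))
}

# Drop flagged breath-hold samples before fitting/scoring.
.activePart <- function(session) {
  keep <- !session@hold
  list(x = session@x[keep], y = session@y[keep])
}

.aggregate <- function(maes, r2s) {
  c(mae = mean(maes), maeSd = if (length(maes) > 1L) stats::sd(maes) else NA_real_,
    r2 = mean(r2s), r2Sd = if (length(r2s) > 1L) stats::sd(r2s) else NA_real_)
}

.scoreOn <- function(model, x, y) {
  yHat <- predict(model, x)
  c(mae = mae(y, yHat), r2 = rSquared(y, yHat))
}

#' Single-regime correspondence model
#'
#' Fits one model on all of the first session and tests it on each remaining
#' session separately; test metrics are reported as mean +/- sd across the
#' test sessions, train metrics as scalars.
#'
#' @param sessions list of at least two [SessionData-class] objects; the
#'   first is the training session.
#' @param degree polynomial degree.
#' @return a [ModelReport-class].
#' @export
runSingleModel <- function(sessions, degree = 3L) {
  if (length(sessions) < 2L)
    stop("the single regime needs at least 2 sessions")
  tr <- .activePart(sessions[[1L]])
  model <- fitPolynomial(tr$x, tr$y, degree,
                         meta = list(regime = "single",
                                     trainSession = sessionId(sessions[[1L]])))
  trainScore <- .scoreOn(model, tr$x, tr$y)
  per <- data.frame(session = sessionId(sessions[[1L]]), partition = "train",
                    mae = trainScore[["mae"]], r2 = trainScore[["r2"]])
  testScores <- lapply(sessions[-1L], function(s) {
    a <- .activePart(s)
    sc <- .scoreOn(model, a$x, a$y)
    data.frame(session = sessionId(s), partition = "test",
               mae = sc[["mae"]], r2 = sc[["r2"]])
  })
  per <- do.call(rbind, c(list(per), testScores))
  tst <- per[per$partition == "test", ]
  .ModelReport(regime = "single", degree = as.integer(degree),
               train = c(mae = trainScore[["mae"]], maeSd = NA_real_,
                         r2 = trainScore[["r2"]], r2Sd = NA_real_),
               test = .aggregate(tst$mae, tst$r2),
               perSession = per, models = list(model))
}

#' Specific-regime correspondence model
#'
#' For each session, fits on its first 70 percent and tests on the held-out
#' 30 percent (chronological split by default). With the random-split mode
#' the split is repeated `nRepeats` times per session under derived seeds.
#' Aggregates are mean +/- sd over all per-session (and per-repeat) results.
#'
#' @param sessions a [SessionData-class] or list of them.
#' @param degree polynomial degree.
#' @param trainFraction train split fraction.
#' @param mode split mode, "chronological" or "random".
#' @param nRepeats random-split repeats per session (ignored when
#'   chronological).
#' @param seed base seed for random splits.
#' @return a [ModelReport-class].
#' @export
runSpecificModel <- function(sessions, degree = 3L, trainFraction = 0.7,
                             mode = c("chronological", "random"),
                             nRepeats = 10L, seed = NULL) {
  mode <- match.arg(mode)
  if (is(sessions, "SessionData")) sessions <- list(sessions)
  if (length(sessions) == 0L) stop("no sessions given")
  if (mode == "random" && is.null(seed))
    stop("random split requires an explicit 'seed'")
  reps <- if (mode == "chronological") 1L else as.integer(nRepeats)
  rows <- list()
  models <- list()
  for (s in sessions) {
    for (r in seq_len(reps)) {
      sp <- splitSession(s, trainFraction, mode = mode,
                         seed = if (mode == "random") seed + 1000L * sessionId(s) + r,
                         minSamples = degree + 2L)
      tr <- .activePart(sp$train); te <- .activePart(sp$test)
      model <- fitPolynomial(tr$x, tr$y, degree,
                             meta = list(regime = "specific",
                                         session = sessionId(s),
                                         split = trainFraction, mode = mode))
      models[[length(models) + 1L]] <- model
      trSc <- .scoreOn(model, tr$x, tr$y)
      teSc <- .scoreOn(model, te$x, te$y)
      rows[[length(rows) + 1L]] <- data.frame(
        session = sessionId(s), partition = c("train", "test"),
        mae = c(trSc[["mae"]], teSc[["mae"]]),
        r2 = c(trSc[["r2"]], teSc[["r2"]]))
    }
  }
  per <- do.call(rbind, rows)
  trn <- per[per$partition == "train", ]
  tst <- per[per$partition == "test", ]
  .ModelReport(regime = "specific", degree = as.integer(degree),
               train = .aggregate(trn$mae, trn$r2),
               test = .aggregate(tst$mae, tst$r2),
               perSession = per, models = models)
}

#' Combined-regime correspondence model
#'
#' Pools the 70 percent train parts of every session, fits one model, and
#' evaluates it on each session's held-out 30 percent. Train metrics are
#' computed per session on its own train part (aggregated mean +/- sd).
#'
#' @param sessions list of [SessionData-class] objects.
#' @param degree polynomial degree.
#' @param trainFraction train split fraction.
#' @param mode split mode (see [splitSession()]).
#' @param seed seed for random splits.
#' @return a [ModelReport-class].
#' @export
runCombinedModel <- function(sessions, degree = 3L, trainFraction = 0.7,
                             mode = c("chronological", "random"), seed = NULL) {
  mode <- match.arg(mode)
  if (length(sessions) == 0L) stop("no sessions given")
  if (mode == "random" && is.null(seed))
    stop("random split requires an explicit 'seed'")
  splits <- lapply(sessions, function(s)
    splitSession(s, trainFraction, mode = mode,
                 seed = if (mode == "random") seed + 1000L * sessionId(s),
                 minSamples = degree + 2L))
  trainParts <- lapply(splits, function(sp) .activePart(sp$train))
  pooledX <- unlist(lapply(trainParts, `[[`, "x"))
  pooledY <- unlist(lapply(trainParts, `[[`, "y"))
  model <- fitPolynomial(pooledX, pooledY, degree,
                         meta = list(regime = "combined",
                                     sessions = vapply(sessions, sessionId,
                                                       integer(1)),
                                     split = trainFraction, mode = mode))
  rows <- lapply(seq_along(sessions), function(i) {
    tr <- trainParts[[i]]
    te <- .activePart(splits[[i]]$test)
    trSc <- .scoreOn(model, tr$x, tr$y)
    teSc <- .scoreOn(model, te$x, te$y)
    data.frame(session = sessionId(sessions[[i]]),
               partition = c("train", "test"),
               mae = c(trSc[["mae"]], teSc[["mae"]]),
               r2 = c(trSc[["r2"]], teSc[["r2"]]))
  })
  per <- do.call(rbind, rows)
  trn <- per[per$partition == "train", ]
  tst <- per[per$partition == "test", ]
  .ModelReport(regime = "combined", degree = as.integer(degree),
               train = .aggregate(trn$mae, trn$r2),
               test = .aggregate(tst$mae, tst$r2),
               perSession = per, models = list(model))
}

#' Held-out degree selection
#'
#' Utility (off by default in the experiment runners): picks the polynomial
#' degree in `degrees` minimizing held-out MAE under the chronological
#' split.
#'
#' @param session a [SessionData-class].
#' @param degrees candidate degrees.
#' @param trainFraction split fraction.
#' @return list(degree, table = data.frame(degree, testMae)).
#' @export
selectDegree <- function(session, degrees = 1:5, trainFraction = 0.7) {
  sp <- splitSession(session, trainFraction, minSamples = max(degrees) + 2L)
  tr <- .activePart(sp$train); te <- .activePart(sp$test)
  maes <- vapply(degrees, function(d) {
    m <- fitPolynomial(tr$x, tr$y, d)
    mae(te$y, predict(m, te$x))
  }, numeric(1))
  list(degree = degrees[which.min(maes)],
       table = data.frame(degree = degrees, testMae = maes))
}
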