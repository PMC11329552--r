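test_that("polynomial OLS reproduces hand-computed fits", {
  # exact linear data
  m1 <- fitPolynomial(0:4, 2 * (0:4) + 1, degree = 1)
  expect_equal(coef(m1), c(1, 2))
  expect_equal(mae(2 * (0:4) + 1, predict(m1, 0:4)), 0)
  # data on y = x^2 with degree 2
  m2 <- fitPolynomial(c(0, 1, 2), c(0, 1, 4), degree = 2)
  expect_equal(coef(m2), c(0, 0, 1))
  # degree-1 fit of (0,0),(1,1),(2,4): slope Sxy/Sxx = 2, intercept -1/3
  m3 <- fitPolynomial(c(0, 1, 2), c(0, 1, 4), degree = 1)
  expect_equal(coef(m3), c(-1 / 3, 2))
  yHat <- predict(m3, c(0, 1, 2))
  expect_equal(yHat, c(-1 / 3, 5 / 3, 11 / 3))
  expect_equal(mae(c(0, 1, 4), yHat), 4 / 9)
  expect_equal(rSquared(c(0, 1, 4), yHat), 100 * 72 / 78)
})

test_that("prediction is Horner evaluation of the coefficients", {
  expect_equal(predict(PolynomialModel(0), c(-1, 0, 3)), c(0, 0, 0))
  expect_equal(predict(PolynomialModel(c(1, 2)), 3), 7)
  expect_equal(predict(PolynomialModel(c(1, 0, 2)), c(0, 2)), c(1, 9))
  expect_error(predict(PolynomialModel(c(1, 2)), NA_real_), "finite")
})

test_that("fit matches brute-force normal equations on random instances", {
  set.seed(202)
  for (rep in 1:6) {
    n <- sample(10:50, 1)
    degree <- sample(1:4, 1)
    x <- runif(n, -2, 5)
    y <- rnorm(n)
    expect_equal(coef(fitPolynomial(x, y, degree)),
                 bruteForcePolyFit(x, y, degree), tolerance = 1e-8)
  }
})

test_that("OLS residuals are orthogonal to the design and SSE is monotone in degree", {
  set.seed(33)
  x <- runif(80, 0, 10)
  y <- 2 + 0.5 * x - 0.1 * x^2 + rnorm(80)
  ssePrev <- Inf
  for (d in 0:4) {
    fit <- fitPolynomial(x, y, d)
    res <- y - predict(fit, x)
    for (k in 0:d)
      expect_lt(abs(sum(res * x^k)) / length(x), 1e-6)
    sse <- sum(res^2)
    expect_lte(sse, ssePrev + 1e-8)
    ssePrev <- sse
  }
})

test_that("noiseless polynomial data are recovered to machine precision", {
  set.seed(5)
  beta <- c(1.5, -2, 0.25, 0.05)
  x <- runif(40, -3, 3)
  y <- predict(PolynomialModel(beta), x)
  for (d in 3:5)
    expect_equal(coef(fitPolynomial(x, y, d))[1:4], beta, tolerance = 1e-8)
})

test_that("degenerate designs and bad arguments are rejected", {
  expect_error(fitPolynomial(rep(1, 10), rnorm(10), 2), "degenerate")
  expect_error(fitPolynomial(1:3, 1:3, 3), "at least")
  expect_error(fitPolynomial(1:4, 1:3, 1), "equal length")
  expect_error(mae(1:3, 1:2), "length")
  expect_warning(r <- rSquared(rep(2, 4), rep(2, 4)), "zero-variance")
  expect_true(is.na(r))
  # basic metric identities
  expect_equal(mae(c(0, 2), c(1, 1)), 1)
  expect_equal(rSquared(c(0, 2), c(1, 1)), 0)
  expect_equal(rSquared(c(0, 2), c(0, 2)), 100)
})

test_that("session splitting is exact on counts and rejects degenerate fractions", {
  s <- makeSession(1L, 1:10, 1:10)
  sp <- splitSession(s, 0.7)
  expect_equal(surrogateValues(sp$train), 1:7)
  expect_equal(surrogateValues(sp$test), 8:10)
  s100 <- makeSession(1L, 1:100, rnorm(100))
  sp100 <- splitSession(s100, 0.7)
  expect_equal(length(surrogateValues(sp100$train)), 70)
  expect_equal(length(surrogateValues(sp100$test)), 30)
  expect_error(splitSession(s, 1.0), "too short")
  # random split needs a seed, covers all samples, reproducible
  expect_error(splitSession(s100, 0.7, mode = "random"), "seed")
  r1 <- splitSession(s100, 0.7, mode = "random", seed = 9L)
  r2 <- splitSession(s100, 0.7, mode = "random", seed = 9L)
  expect_identical(surrogateValues(r1$train), surrogateValues(r2$train))
  expect_equal(sort(c(surrogateValues(r1$train), surrogateValues(r1$test))),
               surrogateValues(s100))
})

test_that("regime runners reproduce closed-form behavior on constructed sessions", {
  x <- seq(0, 10, length.out = 50)
  ident <- lapply(1:3, function(k) makeSession(k, x, x))
  # identical noiseless sessions: all regimes exact
  sing <- runSingleModel(ident, degree = 1)
  expect_equal(sing@test[["mae"]], 0, tolerance = 1e-9)
  expect_equal(sing@test[["r2"]], 100, tolerance = 1e-9)
  spec <- runSpecificModel(ident, degree = 1)
  comb <- runCombinedModel(ident, degree = 1)
  expect_equal(spec@test[["mae"]], 0, tolerance = 1e-9)
  expect_equal(comb@test[["mae"]], spec@test[["mae"]], tolerance = 1e-9)
  # sessions 2 and 3 baseline-shifted by +5: identity fit passes the shift through
  shifted <- list(makeSession(1L, x, x), makeSession(2L, x, x + 5),
                  makeSession(3L, x, x + 5))
  sing5 <- runSingleModel(shifted, degree = 1)
  expect_equal(sing5@test[["mae"]], 5, tolerance = 1e-9)
  expect_error(runSingleModel(shifted[1]), "at least 2")
})

test_that("specific-model test MAE approaches the Gaussian mean absolute deviation", {
  set.seed(77)
  n <- 6000
  x <- runif(n, 0, 30)
  y <- x + rnorm(n)  # 1 mm noise
  rep <- runSpecificModel(makeSession(1L, x, y), degree = 1)
  expect_equal(rep@test[["mae"]], sqrt(2 / pi), tolerance = 0.05)
})

test_that("combined model splits a symmetric baseline difference", {
  # two long sessions y = x +/- 5: pooled OLS fits the central line,
  # leaving a 5 mm per-session error
  x <- seq(0, 10, length.out = 200)
  sessions <- list(makeSession(1L, x, x + 5), makeSession(2L, x, x - 5))
  rep <- runCombinedModel(sessions, degree = 1)
  expect_equal(rep@test[["mae"]], 5, tolerance = 1e-8)
  expect_equal(coef(rep@models[[1]])[2], 1, tolerance = 1e-8)
})

test_that("cubic correspondence parameters are recovered within OLS standard errors", {
  set.seed(404)
  beta <- c(2, 3, -0.15, 0.01)
  n <- 1800
  x <- runif(n, 0, 12)
  y <- predict(PolynomialModel(beta), x) + rnorm(n, 0, 0.5)
  fit <- fitPolynomial(x, y, 3)
  oracle <- lm(y ~ x + I(x^2) + I(x^3))
  expect_equal(coef(fit), unname(coef(oracle)), tolerance = 1e-6)
  se <- sqrt(diag(vcov(oracle)))
  expect_true(all(abs(coef(fit) - beta) < 4 * se))
})

test_that("regime ordering holds on drifted sessions across seeds", {
  # single >= combined >= specific mean test MAE over 20 seeded cohorts
  agree <- 0L
  for (s in 0:19) {
    res <- runClinicalExperiment(list(seed = s, nSubjects = 2L))
    ov <- res$overall
    m <- ov[ov$partition == "test" & ov$metric == "MAE_mm", ]
    v <- setNames(m$mean, m$regime)
    if (v[["single"]] >= v[["combined"]] - 1e-9 &&
        v[["combined"]] >= v[["specific"]] - 1e-9)
      agree <- agree + 1L
  }
  expect_gte(agree, 19L)
})

test_that("held-out degree selection returns a candidate with its score table", {
  set.seed(9)
  x <- runif(300, 0, 10)
  y <- 1 + 2 * x + rnorm(300, 0, 0.3)
  sel <- selectDegree(makeSession(1L, x, y), degrees = 1:4)
  expect_true(sel$degree %in% 1:4)
  expect_equal(nrow(sel$table), 4)
  expect_true(all(sel$table$testMae > 0))
})
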