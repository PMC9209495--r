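test_that("response vector follows the canonical lower-triangle order", {
  m <- 3L
  v <- matrix(0, m, m)
  v[lower.tri(v, diag = TRUE)] <- c(1, 2, 4, 3, 5, 6)  # column-major fill
  v <- v + t(v); diag(v) <- diag(v) / 2
  cm <- ContactMatrix(v, normState = "logcpm")
  y <- buildResponse(cm)
  expect_length(y, 6L)
  # row-major order: (0,0), (1,0), (1,1), (2,0), (2,1), (2,2)
  expect_equal(y, c(v[1, 1], v[2, 1], v[2, 2], v[3, 1], v[3, 2], v[3, 3]))
  expect_length(buildResponse(ContactMatrix(matrix(0, 200, 200),
                                            normState = "logcpm")), 20100L)
  expect_error(buildResponse(ContactMatrix(matrix(0, 3, 3))), "logCPM")
})

test_that("design value is log(m/(d+1)), zero at the far corner", {
  expect_equal(designValue(199, 200), 0)
  expect_equal(designValue(0, 200), log(200))
  expect_lt(abs(designValue(0, 200) - 5.2983), 1e-4)
  d <- 0:99
  expect_true(all(diff(designValue(d, 100)) < 0))
  expect_equal(designValue(9, 100, logBase = 10), 1)
  expect_error(designValue(-1, 100), "d must be >= 0")
})

test_that("pairs contained in no candidate contribute nothing", {
  m <- 10L
  cand <- data.frame(start = 0L, end = 5L)
  yhat <- predictResponse(1, cand, m)
  idx <- pairIndices(m)
  outside <- idx$i >= 5L | idx$j >= 5L
  expect_true(all(yhat[outside] == 0))
  expect_true(all(yhat[!outside] == log(m / (idx$d[!outside] + 1))))
})

test_that("FTRL leaves a zero response at zero coefficients", {
  m <- 15L
  cand <- assembleCandidates(c(0L, 5L, 10L, 15L), m)
  fit <- fitFTRL(numeric(m * (m + 1) / 2), cand, m, epochs = 3)
  expect_true(all(fit$coefficients == 0))
})

test_that("FTRL recovers a single coefficient within 1% in 10 epochs", {
  m <- 20L
  cand <- data.frame(start = 0L, end = m)
  y <- 0.7 * designValue(pairIndices(m)$d, m)
  fit <- fitFTRL(y, cand, m, epochs = 10L)
  expect_lt(abs(fit$coefficients - 0.7) / 0.7, 0.01)
})

test_that("FTRL matches the batch nonnegative-lasso oracle on a fixed instance", {
  # canonical tiling {0,5,10,15,20} plus the meta [0,10); oracle penalty
  # l1/epochs from the follow-the-leader correspondence
  m <- 20L
  cand <- data.frame(start = c(0L, 0L, 5L, 10L, 15L),
                     end = c(5L, 10L, 10L, 15L, 20L))
  X <- denseDesign(cand, m)
  btrue <- c(0.4, 0.3, 0.6, 0.5, 0.35)
  set.seed(11)
  y <- X %*% btrue + rnorm(nrow(X), 0, 0.05)
  fit <- fitFTRL(y, cand, m, epochs = 10L, l1 = 3, alpha = 0.3)
  bo <- nnlassoCD(X, y, lam = 3 / 10)
  sup <- which(bo > 1e-8)
  expect_gt(length(sup), 3L)
  expect_lt(max(abs(fit$coefficients[sup] - bo[sup]) / bo[sup]), 0.05)
})

test_that("large enough l1 forces exact sparsity", {
  m <- 15L
  cand <- assembleCandidates(c(0L, 5L, 10L, 15L), m)
  set.seed(12)
  y <- abs(rnorm(m * (m + 1) / 2))
  X <- denseDesign(cand, m)
  epochs <- 4L
  bound <- epochs * max(abs(crossprod(X, y)))
  fit <- fitFTRL(y, cand, m, epochs = epochs, l1 = bound * 1.01)
  expect_true(all(fit$coefficients == 0))
})

test_that("fitted matrix re-bins predictions symmetrically", {
  m <- 12L
  cand <- data.frame(start = c(0L, 6L), end = c(6L, 12L))
  fm <- fittedMatrix(c(0.5, 0.2), cand, m)
  v <- cmValues(fm)
  expect_equal(v, t(v))
  expect_equal(v[3, 2], 0.5 * designValue(1, m))
  expect_equal(v[9, 8], 0.2 * designValue(1, m))
  expect_equal(v[8, 3], 0)           # cross pair in no candidate
  expect_true(all(cmValues(fittedMatrix(c(0, 0), cand, m)) == 0))
})

test_that("reported R^2 agrees with the direct definition", {
  m <- 15L
  cand <- assembleCandidates(c(0L, 5L, 10L, 15L), m)
  set.seed(13)
  btrue <- runif(nrow(cand), 0, 0.5)
  y <- predictResponse(btrue, cand, m) + rnorm(m * (m + 1) / 2, 0, 0.1)
  fit <- fitFTRL(y, cand, m, epochs = 5L)
  yhat <- predictResponse(fit$coefficients, fit$candidates, m)
  expect_equal(unname(fit$r2), rSquared(y, yhat))
  expect_equal(rSquared(y, y), 1)
})

test_that("identical replicates match a single fit with scaled exposure", {
  m <- 40L
  cand <- assembleCandidates(c(0L, 8L, 15L, 26L, 33L, 40L), m)
  set.seed(14)
  btrue <- runif(nrow(cand), 0, 0.6)
  y <- predictResponse(btrue, cand, m) + rnorm(m * (m + 1) / 2, 0, 0.05)
  f3 <- fitFTRL(cbind(y, y, y), cand, m, epochs = 2L)
  f1 <- fitFTRL(y, cand, m, epochs = 6L)
  expect_identical(f3$coefficients, f1$coefficients)
})

test_that("R^2 never decreases with epochs on a noiseless problem", {
  m <- 60L
  cand <- assembleCandidates(c(0L, 7L, 15L, 20L, 28L, 37L, 45L, 52L, 60L),
                             m, maxSize = 20)
  set.seed(15)
  btrue <- ifelse(runif(nrow(cand)) < 0.5, runif(nrow(cand), 0.1, 0.8), 0)
  y <- predictResponse(btrue, cand, m)
  fit <- fitFTRL(y, cand, m, epochs = 10L)
  expect_true(all(diff(fit$history$r2) >= -1e-12))
})

test_that("input contracts are enforced", {
  m <- 10L
  cand <- data.frame(start = 0L, end = 5L)
  y <- numeric(m * (m + 1) / 2)
  expect_error(fitFTRL(y, cand, m, epochs = 0L), "epochs")
  expect_error(fitFTRL(y[-1], cand, m), "m\\(m\\+1\\)/2")
  y2 <- y; y2[7] <- NA
  expect_error(fitFTRL(y2, cand, m), "non-finite response at row 7")
  expect_error(fitFTRL(y, data.frame(start = 3L, end = 2L), m), "start < end")
})
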