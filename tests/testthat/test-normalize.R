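test_that("ICE leaves balanced matrices unchanged up to scale", {
  # 2x2 off-diagonal matrix is already balanced
  cm <- ContactMatrix(matrix(c(0, 7, 7, 0), 2))
  out <- iceNormalize(cm)
  expect_equal(cmValues(out), cmValues(cm))
  expect_identical(normState(out), "iced")

  # equal row sums: output proportional to input (here equal, since the
  # total is conserved)
  v <- matrix(1, 4, 4); diag(v) <- 0
  out <- iceNormalize(ContactMatrix(v))
  expect_equal(cmValues(out), v)
})

test_that("ICE equalizes unmasked row sums and conserves total mass", {
  set.seed(3)
  v <- matrix(runif(400, 0.5, 4), 20)
  v <- v + t(v)
  cm <- ContactMatrix(v)
  tol <- 1e-6
  out <- iceNormalize(cm, maxIter = 500L, tol = tol)
  meta <- cmMetadata(out)
  expect_true(meta$ice_converged)
  keep <- setdiff(seq_len(20), meta$ice_masked + 1L)
  rs <- rowSums(cmValues(out))[keep]
  expect_lt(stats::sd(rs) / mean(rs), tol)
  expect_lt(abs(sum(cmValues(out)) - sum(v)) / sum(v), 1e-9)
  # symmetry preserved
  expect_lt(max(abs(cmValues(out) - t(cmValues(out)))), 1e-9)
})

test_that("ICE warns and flags when the iteration budget is exhausted", {
  set.seed(4)
  v <- matrix(runif(100, 0.1, 5), 10)
  v <- v + t(v)
  expect_warning(out <- iceNormalize(ContactMatrix(v), maxIter = 1L),
                 "did not converge")
  expect_false(cmMetadata(out)$ice_converged)
})

test_that("logCPM matches Eq-style arithmetic and tracks state", {
  # zero entries map to log10(s) = 0 at s = 1
  v <- matrix(c(0, 2, 2, 0), 2)
  out <- logCPM(ContactMatrix(v))
  expect_equal(cmValues(out)[1, 1], 0)
  # an entry equal to L * 1e-6 has CPM term 1 -> log10(2)
  m <- 40L
  v <- matrix(0, m, m)
  v[2, 1] <- v[1, 2] <- 4e6
  v[4, 3] <- v[3, 4] <- 4  # the probe entry: 4 / L * 1e6 = 1
  out <- logCPM(ContactMatrix(v))
  expect_equal(cmMetadata(out)$logcpm_library_size, 4e6 + 4)
  expect_equal(cmValues(out)[4, 3], log10(4 / (4e6 + 4) * 1e6 + 1))
  expect_lt(abs(cmValues(out)[4, 3] - log10(2)), 1e-6)
  expect_identical(normState(out), "logcpm")
  # monotone in the input for fixed L, and state guards
  expect_error(logCPM(out), "already")
  expect_error(logCPM(ContactMatrix(matrix(0, 3, 3))), "library size L is zero")
  expect_error(logCPM(ContactMatrix(v), s = 0.5), "s must be >= 1")
})

test_that("logCPM is monotone in the interaction frequency", {
  set.seed(5)
  v <- matrix(rpois(64, 20), 8)
  v <- v + t(v)
  out <- cmValues(logCPM(ContactMatrix(v)))
  o <- order(v)
  expect_true(all(diff(out[o]) >= 0))
})

test_that("pseudo matrix is the element-wise geometric mean", {
  a <- matrix(c(0, 1, 1, 4), 2)
  b <- matrix(c(0, 4, 4, 9), 2)
  pa <- ContactMatrix(a); pb <- ContactMatrix(b)
  # identical replicates -> identity
  expect_equal(cmValues(pseudoMatrix(list(pa, pa))), a)
  # sqrt(1 * 4) = 2 off-diagonal; zero anywhere forces zero
  p <- cmValues(pseudoMatrix(list(pa, pb)))
  expect_equal(p[2, 1], 2)
  expect_equal(p[1, 1], 0)
  expect_equal(p[2, 2], 6)
  # mixed normalization states are a contract violation
  expect_error(pseudoMatrix(list(pa, logCPM(pb))), "share")
})

test_that("downsampling conserves exact totals and is seed-reproducible", {
  set.seed(6)
  v <- matrix(rpois(15^2, 6), 15)
  v <- v + t(v)
  cm <- ContactMatrix(v)
  N <- sum(cmValues(cm)[lower.tri(cmValues(cm), diag = TRUE)])
  # fraction 1 returns the input untouched
  expect_equal(cmValues(downsampleMatrix(cm, 1, seed = 1)), cmValues(cm))
  for (f in c(1 / 2, 1 / 3)) {
    d <- downsampleMatrix(cm, f, seed = 9)
    tot <- sum(cmValues(d)[lower.tri(cmValues(d), diag = TRUE)])
    expect_identical(tot, floor(f * N))
    # per-cell counts never exceed the originals
    expect_true(all(cmValues(d) <= cmValues(cm)))
  }
  expect_equal(downsampleMatrix(cm, 0.5, seed = 9),
               downsampleMatrix(cm, 0.5, seed = 9))
  expect_error(downsampleMatrix(ContactMatrix(matrix(c(0, .5, .5, 0), 2)),
                                0.5, seed = 1), "integer counts")
})

test_that("downsampled cell means follow the hypergeometric expectation", {
  v <- matrix(c(40, 20, 20, 80), 2)
  cm <- ContactMatrix(v)
  f <- 0.5
  draws <- vapply(1:200, function(s) {
    cmValues(downsampleMatrix(cm, f, seed = s))[2, 1]
  }, numeric(1))
  expectMean <- f * v[2, 1]
  se <- stats::sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - expectMean), 3 * se + 1e-9)
})

test_that("two half down-samplings match one quarter down-sampling in mean", {
  set.seed(8)
  v <- matrix(rpois(100, 12), 10)
  v <- v + t(v)
  cm <- ContactMatrix(v)
  cell <- c(4, 2)
  twice <- vapply(1:150, function(s) {
    cmValues(downsampleMatrix(downsampleMatrix(cm, 0.5, seed = s),
                              0.5, seed = s + 1000))[cell[1], cell[2]]
  }, numeric(1))
  quarter <- vapply(1:150, function(s) {
    cmValues(downsampleMatrix(cm, 0.25, seed = s + 2000))[cell[1], cell[2]]
  }, numeric(1))
  se <- sqrt(stats::var(twice) / 150 + stats::var(quarter) / 150)
  expect_lt(abs(mean(twice) - mean(quarter)), 3 * se + 1e-9)
})
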