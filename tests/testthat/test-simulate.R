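test_that("layer-1 tiling is disjoint with sizes in the base range", {
  for (seed in 1:5) {
    tr <- generateHierarchy(simConfig(m = 200L), seed = seed)
    l1 <- tr@layers[[1]]
    sizes <- l1$end - l1$start
    expect_true(all(sizes >= 3L & sizes <= 20L))
    expect_equal(l1$start, c(0L, l1$end[-nrow(l1)]))  # tiles, no gaps
    expect_equal(l1$end[nrow(l1)], 200L)
  }
})

test_that("hierarchy is nested without POP and fails nesting exactly on POP pairs", {
  cfg0 <- simConfig(m = 300L, popFraction = 0)
  tr0 <- generateHierarchy(cfg0, seed = 11)
  expect_equal(nrow(tr0@popTads), 0L)
  expect_false(any(classifyPartialOverlap(tr0@allTads)))

  cfg1 <- simConfig(m = 400L, popFraction = 0.15)
  tr1 <- generateHierarchy(cfg1, seed = 11)
  expect_gt(nrow(tr1@popTads), 0L)
  flags <- classifyPartialOverlap(tr1@allTads)
  flagged <- tr1@allTads[flags, c("start", "end")]
  popIv <- unique(rbind(
    data.frame(start = tr1@popTads$a_start, end = tr1@popTads$a_end),
    data.frame(start = tr1@popTads$b_start, end = tr1@popTads$b_end)))
  expect_setequal(paste(flagged$start, flagged$end),
                  paste(popIv$start, popIv$end))
  # every POP pair intersects exactly on its picked base TAD
  for (r in seq_len(nrow(tr1@popTads))) {
    p <- tr1@popTads[r, ]
    expect_equal(max(p$a_start, p$b_start), p$base_start)
    expect_equal(min(p$a_end, p$b_end), p$base_end)
    expect_true(paste(p$base_start, p$base_end) %in%
                  paste(tr1@layers[[1]]$start, tr1@layers[[1]]$end))
  }
})

test_that("no boundary removal leaves layers equal apart from POP additions", {
  tr <- generateHierarchy(simConfig(m = 150L, boundaryRemoval = 0,
                                    popFraction = 0), seed = 3)
  expect_identical(tr@layers[[1]], tr@layers[[2]])
  expect_identical(tr@layers[[1]], tr@layers[[3]])
})

test_that("mean matrix follows the three-component decay model", {
  cfg <- simConfig(m = 60L, boundaryRemoval = 0, popFraction = 0,
                   loopFraction = 0)
  tr <- generateHierarchy(cfg, seed = 21)
  mu <- meanMatrix(tr, cfg)
  # identical layers de-duplicate: single-cover diagonal pairs sit at Kt
  i <- tr@layers[[1]]$start[2] + 1L
  expect_equal(mu[i, i], 28)
  # decay with distance inside a TAD: Kt * (d + 1)^c
  tad <- tr@layers[[1]][2, ]
  if (tad$end - tad$start >= 3) {
    expect_equal(mu[tad$start + 3, tad$start + 1], 28 * 3^-0.69)
  }
  # cross-boundary pair outside all TADs, no loop, no noise -> 0
  b <- tr@layers[[1]]$end[2]
  expect_equal(mu[b + 1, b], 0)
  # a noise pair outside TADs adds exactly Knoise
  noise <- data.frame(i = b, j = b - 1L)   # 0-based cross pair
  mu2 <- meanMatrix(tr, cfg, noise)
  expect_equal(mu2[b + 1, b], 2)
  # nested cover doubles the TAD term
  cfgN <- simConfig(m = 60L, boundaryRemoval = 0.4, popFraction = 0,
                    loopFraction = 0)
  trN <- generateHierarchy(cfgN, seed = 22)
  merged <- trN@layers[[2]]
  wide <- merged[(merged$end - merged$start) >
                   max(trN@layers[[1]]$end - trN@layers[[1]]$start), ]
  if (nrow(wide) > 0) {
    muN <- meanMatrix(trN, cfgN)
    inner <- trN@layers[[1]]$start[trN@layers[[1]]$start >= wide$start[1] &
                                     trN@layers[[1]]$end <= wide$end[1]][1]
    expect_gte(muN[inner + 1, inner + 1] / 28, 2)
  }
})

test_that("NB sampler reproduces mean and dispersion moments", {
  set.seed(31)
  x <- rnbinomDisp(10000, 28, 0.01)
  expect_lt(abs(mean(x) - 28), 3 * stats::sd(x) / sqrt(10000))
  expect_lt(abs(stats::var(x) - 35.84) / 35.84, 0.10)
  # dispersion zero falls back to the Poisson limit
  y <- rnbinomDisp(10000, 7, 0)
  expect_lt(abs(stats::var(y) - 7) / 7, 0.05)
})

test_that("replicates share TADs, differ in noise, and are seed-stable", {
  cfg <- simConfig(m = 80L, k = 3L)
  tr <- generateHierarchy(cfg, seed = 41)
  s1 <- sampleReplicates(tr, cfg, seed = 42)
  s2 <- sampleReplicates(tr, cfg, seed = 42)
  expect_identical(lapply(1:3, function(i) cmValues(s1$replicates[[i]])),
                   lapply(1:3, function(i) cmValues(s2$replicates[[i]])))
  # per-replicate noise sets resampled independently
  expect_false(identical(s1$truth@noiseSets[[1]], s1$truth@noiseSets[[2]]))
  npairs <- 80 * 81 / 2
  nNoise <- nrow(s1$truth@noiseSets[[1]])
  expect_equal(nNoise, round(0.04 * npairs))
  # counts are nonnegative integers, zero where mu = 0
  v <- cmValues(s1$replicates[[1]])
  expect_true(all(v == round(v) & v >= 0))
  mu <- meanMatrix(tr, cfg, s1$truth@noiseSets[[1]])
  expect_true(all(v[mu == 0] == 0))
})

test_that("sampled counts converge to the configured mean", {
  cfg <- simConfig(m = 40L, boundaryRemoval = 0, popFraction = 0,
                   loopFraction = 0, noiseFraction = 0, k = 1L)
  tr <- generateHierarchy(cfg, seed = 51)
  i <- tr@layers[[1]]$start[2] + 1L   # single-cover diagonal cell, mu = 28
  draws <- vapply(1:600, function(s) {
    cmValues(sampleReplicates(tr, cfg, seed = s)$replicates[[1]])[i, i]
  }, numeric(1))
  se <- stats::sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 28), 3 * se)
})

test_that("campaign emits the full matrix grid with shared per-setting truth", {
  camp <- simulateCampaign(noiseLevels = c(0.04, 0.12), repsPerLevel = 2L,
                           popFractions = c(0.15, 0),
                           config = simConfig(m = 100L), seed = 5)
  expect_length(camp, 4L)
  expect_equal(sum(vapply(camp, function(s) nReplicates(s$replicates),
                          integer(1))), 8L)
  for (s in camp) {
    expect_equal(nReplicates(s$replicates), 2L)
    expect_s4_class(s$truth, "GroundTruth")
  }
  noPop <- vapply(camp, function(s) s$popFraction == 0, logical(1))
  expect_true(all(vapply(camp[noPop], function(s)
    nrow(s$truth@popTads) == 0L, logical(1))))
})

test_that("ground truth round-trips through the BED-like export", {
  tr <- generateHierarchy(simConfig(m = 120L), seed = 61)
  path <- withr::local_tempfile()
  writeGroundTruth(tr, path)
  back <- readTadSet(path)
  expect_setequal(paste(back$start, back$end),
                  paste(tr@allTads$start, tr@allTads$end))
})
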