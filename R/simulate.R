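#' Simulator configuration
#'
#' Defaults reproduce the study conditions of the built-in simulation:
#' about 400 bins of base TADs sized 3--20 bins, in-TAD scale Kt = 28,
#' loop scale Kd = 2 Kt = 56, noise mean 2, power-law decay exponent
#' -0.69 with distance offset 1, NB dispersion 0.01, 0.01% loop pairs,
#' 25% boundary removal per layer, 15% of base TADs spawning partially
#' overlapping meta-TAD couples, and 5 replicates.
#'
#' @param m bin count.
#' @param Kt,Kd,Knoise signal scales (in-TAD, loop, noise).
#' @param decay power-law decay exponent (negative).
#' @param prior distance offset added before the decay is applied.
#' @param dispersion NB dispersion (variance = mu + dispersion mu^2).
#' @param loopFraction fraction of lower-triangle pairs made loops.
#' @param noiseFraction per-replicate fraction of pairs made noise.
#' @param popFraction fraction of base TADs picked for partial overlap.
#' @param boundaryRemoval fraction of internal boundaries removed per layer.
#' @param baseSizeRange base-TAD size range in bins (inclusive).
#' @param k replicate count.
#' @return A \linkS4class{SimulationConfig}.
#' @export
simConfig <- function(m = 400L, Kt = 28, Kd = 56, Knoise = 2,
                      decay = -0.69, prior = 1, dispersion = 0.01,
                      loopFraction = 1e-4, noiseFraction = 0.04,
                      popFraction = 0.15, boundaryRemoval = 0.25,
                      baseSizeRange = c(3L, 20L), k = 5L) {
  new("SimulationConfig",
      m = as.integer(m), Kt = Kt, Kd = Kd, Knoise = Knoise,
      decay = decay, prior = prior, dispersion = dispersion,
      loopFraction = loopFraction, noiseFraction = noiseFraction,
      popFraction = popFraction, boundaryRemoval = boundaryRemoval,
      baseSizeMin = as.integer(baseSizeRange[1L]),
      baseSizeMax = as.integer(baseSizeRange[2L]), k = as.integer(k))
}

# tile [0, m) with sizes uniform in [lo, hi]; returns data.frame(start, end)
.tileChromosome <- function(m, lo, hi) {
  sizes <- integer(0)
  remaining <- m
  while (remaining > hi) {
    s <- sample(lo:hi, 1L)
    if (remaining - s != 0L && remaining - s < lo) next  # avoid stub < lo
    sizes <- c(sizes, s)
    remaining <- remaining - s
  }
  if (remaining > 0L) sizes <- c(sizes, remaining)
  ends <- cumsum(sizes)
  data.frame(start = c(0L, ends[-length(ends)]), end = ends)
}

# merge a tiling by dropping a fraction of its internal boundaries;
# 'protect' boundaries are never dropped
.removeBoundaries <- function(tiling, fraction, protect = integer(0)) {
  internal <- tiling$end[-nrow(tiling)]
  eligible <- setdiff(internal, protect)
  nDrop <- floor(fraction * length(internal))
  nDrop <- min(nDrop, length(eligible))
  drop <- if (nDrop > 0L) sample(eligible, nDrop) else integer(0)
  keep <- sort(setdiff(internal, drop))
  ends <- c(keep, tiling$end[nrow(tiling)])
  data.frame(start = c(0L, ends[-length(ends)]), end = ends)
}

#' Generate a ground-truth TAD hierarchy
#'
#' Stacks three layers of artificial TADs. Layer 1 tiles the chromosome
#' with disjoint base TADs; layers 2 and 3 are produced by randomly
#' removing a fraction of the internal boundaries of the layer below.
#' After the layer-2 removal, a fraction of the (unmerged, interior)
#' base TADs are picked and each replaced by a couple of meta-TADs --
#' one spanning the picked TAD plus its upstream neighbour, the other
#' the picked TAD plus its downstream neighbour -- which therefore
#' partially overlap exactly on the picked base TAD. Loop positions are
#' sampled uniformly over lower-triangle bin pairs.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param seed integer seed.
#' @return A \linkS4class{GroundTruth}.
#' @export
generateHierarchy <- function(config = simConfig(), seed = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  withSeed(seed, {
    m <- config@m
    tiling1 <- .tileChromosome(m, config@baseSizeMin, config@baseSizeMax)
    tiling2 <- .removeBoundaries(tiling1, config@boundaryRemoval)
    popTads <- data.frame(
      a_start = integer(0), a_end = integer(0),
      b_start = integer(0), b_end = integer(0),
      base_start = integer(0), base_end = integer(0))
    layer2 <- tiling2
    protect3 <- integer(0)
    if (config@popFraction > 0) {
      # picked TADs: base TADs that survive the merge intact, with both
      # neighbours, spaced >= 3 tiling elements apart
      isBase <- paste(tiling2$start, tiling2$end) %in%
        paste(tiling1$start, tiling1$end)
      interior <- seq_len(nrow(tiling2)) > 1L &
        seq_len(nrow(tiling2)) < nrow(tiling2)
      eligible <- which(isBase & interior)
      nPick <- round(config@popFraction * nrow(tiling1))
      picked <- integer(0)
      for (cand in sample(eligible)) {
        if (length(picked) >= nPick) break
        if (all(abs(cand - picked) >= 3L)) picked <- c(picked, cand)
      }
      if (length(picked) < nPick && length(eligible) == 0L) {
        warning("no interior base TAD available for partial overlaps")
      }
      picked <- sort(picked)
      if (length(picked) > 0L) {
        metaA <- data.frame(start = tiling2$start[picked - 1L],
                            end = tiling2$end[picked])
        metaB <- data.frame(start = tiling2$start[picked],
                            end = tiling2$end[picked + 1L])
        popTads <- data.frame(
          a_start = metaA$start, a_end = metaA$end,
          b_start = metaB$start, b_end = metaB$end,
          base_start = tiling2$start[picked], base_end = tiling2$end[picked])
        keep <- setdiff(seq_len(nrow(tiling2)), picked)
        layer2 <- rbind(tiling2[keep, ], metaA, metaB)
        layer2 <- layer2[order(layer2$start, layer2$end), ]
        rownames(layer2) <- NULL
        # keep layer 3 from cutting across a POP construction
        protect3 <- unique(c(metaA$start, metaA$end, metaB$start, metaB$end))
      }
    }
    tiling3 <- .removeBoundaries(tiling2, config@boundaryRemoval, protect3)
    layers <- list(tiling1, layer2, tiling3)
    all <- rbind(
      cbind(tiling1, layer = 1L),
      cbind(layer2, layer = 2L),
      cbind(tiling3, layer = 3L))
    all <- all[!duplicated(all[, c("start", "end")]), ]
    all <- all[order(all$start, all$end), ]
    rownames(all) <- NULL
    all$pop <- paste(all$start, all$end) %in%
      c(paste(popTads$a_start, popTads$a_end),
        paste(popTads$b_start, popTads$b_end))
    nLoop <- round(config@loopFraction * m * (m + 1) / 2)
    loops <- .samplePairs(m, nLoop)
    new("GroundTruth", layers = layers, allTads = all, loops = loops,
        noiseSets = list(), popTads = popTads, m = m)
  })
}

# sample n distinct lower-triangle (incl. diagonal) bin pairs, 0-based
.samplePairs <- function(m, n) {
  npairs <- m * (m + 1) / 2
  t <- sample.int(npairs, min(n, npairs)) - 1
  i <- floor((sqrt(8 * t + 1) - 1) / 2)
  j <- t - i * (i + 1) / 2
  data.frame(i = as.integer(i), j = as.integer(j))
}

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", object@m, "bins;",
      vapply(object@layers, nrow, integer(1)), "TADs per layer;",
      nrow(object@popTads), "partially overlapping couples;",
      nrow(object@loops), "loops\n")
})

#' Expected contact matrix of a simulated replicate
#'
#' Builds the NB mean matrix mu. On the hypothesis that each interaction
#' frequency reflects the cumulative effect of the hierarchical TADs it
#' falls in, every distinct ground-truth TAD containing a bin pair
#' contributes \code{Kt (d + prior)^decay} once (d = bin distance); loop
#' pairs add \code{Kd (d + prior)^decay} and noise pairs a flat
#' \code{Knoise}.
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param config the matching \linkS4class{SimulationConfig}.
#' @param noisePairs data.frame (i, j) of 0-based noise bin pairs for one
#'   replicate (NULL for none).
#' @return A symmetric m x m numeric matrix of means.
#' @export
meanMatrix <- function(truth, config, noisePairs = NULL) {
  stopifnot(is(truth, "GroundTruth"), is(config, "SimulationConfig"))
  m <- truth@m
  cover <- matrix(0, m, m)
  tads <- truth@allTads
  for (r in seq_len(nrow(tads))) {
    idx <- (tads$start[r] + 1L):tads$end[r]
    cover[idx, idx] <- cover[idx, idx] + 1
  }
  d <- abs(outer(seq_len(m), seq_len(m), `-`))
  decayTerm <- (d + config@prior)^config@decay
  mu <- cover * config@Kt * decayTerm
  if (nrow(truth@loops) > 0L) {
    li <- truth@loops$i + 1L
    lj <- truth@loops$j + 1L
    mu[cbind(li, lj)] <- mu[cbind(li, lj)] +
      config@Kd * decayTerm[cbind(li, lj)]
    off <- li != lj
    mu[cbind(lj[off], li[off])] <- mu[cbind(li[off], lj[off])]
  }
  if (!is.null(noisePairs) && nrow(noisePairs) > 0L) {
    ni <- noisePairs$i + 1L
    nj <- noisePairs$j + 1L
    mu[cbind(ni, nj)] <- mu[cbind(ni, nj)] + config@Knoise
    off <- ni != nj
    mu[cbind(nj[off], ni[off])] <- mu[cbind(ni[off], nj[off])]
  }
  mu
}

#' Negative-binomial draws parameterized by mean and dispersion
#'
#' Samples counts with mean \code{mu} and variance
#' \code{mu + dispersion * mu^2}; \code{dispersion = 0} gives the Poisson
#' limit. Cells with \code{mu = 0} are always 0.
#'
#' @param n number of draws.
#' @param mu mean (scalar or length-n vector).
#' @param dispersion NB dispersion.
#' @return Integer-valued numeric vector of counts.
#' @export
rnbinomDisp <- function(n, mu, dispersion) {
  if (dispersion == 0) return(stats::rpois(n, mu))
  stats::rnbinom(n, size = 1 / dispersion, mu = mu)
}

#' Sample contact-matrix replicates from a ground truth
#'
#' Draws k replicate matrices. TADs and loops are shared; noise positions
#' are re-sampled independently per replicate (the per-replicate noise
#' pair sets are returned in the updated ground truth).
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param config a \linkS4class{SimulationConfig}.
#' @param seed integer seed; a fixed seed gives a bit-identical set.
#' @return A list with elements \code{replicates}
#'   (\linkS4class{ReplicateSet} of raw matrices) and \code{truth} (the
#'   input with \code{noiseSets} filled in).
#' @export
sampleReplicates <- function(truth, config, seed = NULL) {
  stopifnot(is(truth, "GroundTruth"), is(config, "SimulationConfig"))
  m <- truth@m
  nNoise <- round(config@noiseFraction * m * (m + 1) / 2)
  withSeed(seed, {
    low <- lower.tri(matrix(0, m, m), diag = TRUE)
    mats <- vector("list", config@k)
    noiseSets <- vector("list", config@k)
    for (r in seq_len(config@k)) {
      noiseSets[[r]] <- .samplePairs(m, nNoise)
      mu <- meanMatrix(truth, config, noiseSets[[r]])
      v <- matrix(0, m, m)
      v[low] <- rnbinomDisp(sum(low), mu[low], config@dispersion)
      v <- v + t(v)
      diag(v) <- diag(v) / 2
      mats[[r]] <- ContactMatrix(v, chrom = "chrS", normState = "raw",
                                 metadata = list(replicate = r, seed = seed))
    }
    truth@noiseSets <- noiseSets
    list(replicates = ReplicateSet(mats), truth = truth)
  })
}

#' Run a simulation campaign
#'
#' Produces, for every combination of noise level and partial-overlap
#' setting, one ground truth and \code{repsPerLevel} replicate matrices
#' (replicates within a setting share TADs and loops and differ only in
#' noise). The default campaign -- five noise levels (4--20%), five
#' replicates, POP fractions 15% and 0 -- yields 50 matrices from 10
#' ground truths.
#'
#' @param noiseLevels numeric vector of noise fractions.
#' @param repsPerLevel replicates per setting.
#' @param popFractions numeric vector of partial-overlap fractions.
#' @param config base \linkS4class{SimulationConfig}.
#' @param seed integer seed.
#' @return A list of settings, each with \code{config}, \code{truth} and
#'   \code{replicates}.
#' @export
simulateCampaign <- function(noiseLevels = c(0.04, 0.08, 0.12, 0.16, 0.20),
                             repsPerLevel = 5L,
                             popFractions = c(0.15, 0),
                             config = simConfig(), seed = 1L) {
  out <- list()
  idx <- 0L
  for (pop in popFractions) {
    for (noise in noiseLevels) {
      idx <- idx + 1L
      cfg <- config
      cfg@popFraction <- pop
      cfg@noiseFraction <- noise
      cfg@k <- as.integer(repsPerLevel)
      truth <- generateHierarchy(cfg, seed = seed + 1000L * idx)
      sim <- sampleReplicates(truth, cfg, seed = seed + 1000L * idx + 500L)
      out[[idx]] <- list(config = cfg, truth = sim$truth,
                         replicates = sim$replicates,
                         noiseLevel = noise, popFraction = pop)
    }
  }
  out
}

#' Export / import ground-truth TADs as BED-like text
#'
#' Columns: chrom, start, end, layer, pop_flag. Coordinates are written
#' in base pairs when \code{resolution > 0}, otherwise in bins.
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param path file path.
#' @param resolution base pairs per bin (0 = bins).
#' @param chrom chromosome label.
#' @export
writeGroundTruth <- function(truth, path, resolution = 0L, chrom = "chrS") {
  scale <- if (resolution > 0L) resolution else 1L
  df <- data.frame(chrom = chrom,
                   start = truth@allTads$start * scale,
                   end = truth@allTads$end * scale,
                   layer = truth@allTads$layer,
                   pop_flag = as.integer(truth@allTads$pop))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED-like TAD interval file
#'
#' Accepts 3+ column text (chrom, start, end, ...); returns bin intervals
#' obtained by dividing by \code{resolution} when it is positive.
#'
#' @param path file path.
#' @param resolution base pairs per bin (0 = coordinates already in bins).
#' @return data.frame with columns start, end (half-open).
#' @export
readTadSet <- function(path, resolution = 0L) {
  df <- utils::read.table(path, header = FALSE)
  if (ncol(df) < 3L) stop("TAD file must have >= 3 columns")
  scale <- if (resolution > 0L) resolution else 1L
  out <- data.frame(start = as.numeric(df[[2L]]) / scale,
                    end = as.numeric(df[[3L]]) / scale)
  out[!duplicated(out), , drop = FALSE]
}
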