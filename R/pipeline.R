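#' Call significant hierarchical TADs on contact-matrix replicates
#'
#' End-to-end pipeline: each raw replicate is ICE-balanced and
#' logCPM-transformed; a pseudo contact matrix (element-wise geometric
#' mean) provides consensus TAD boundaries via diamond insulation (or an
#' injected external boundary list); boundaries are assembled into
#' all-pairs candidate hierarchical TADs; shared nonnegative sparse
#' coefficients are fitted across replicates by FTRL-Proximal; and a
#' right-tailed permutation test on independent per-replicate fits
#' screens the significant disjoint, nested and partially overlapping
#' TADs. With a single input matrix the permutation test falls back to
#' within-distance-stratum bootstrap refits.
#'
#' @param reps a \linkS4class{ReplicateSet}, a single
#'   \linkS4class{ContactMatrix}, or a list of matrices.
#' @param boundaries optional externally supplied boundary cut positions
#'   (bins); skips the internal boundary caller.
#' @param w diamond window in bins.
#' @param filterAlpha rank-sum filter level of the boundary caller.
#' @param minSize,maxSize candidate TAD size window in bins.
#' @param maxSizeBp optional maximum TAD size in base pairs (converted
#'   via the matrix resolution; overrides \code{maxSize}).
#' @param alpha,beta,l1,epochs FTRL hyperparameters (see
#'   \code{\link{fitFTRL}}).
#' @param cutoff permutation-test significance cutoff.
#' @param tau coefficient screening threshold.
#' @param nBoot bootstrap resamples for the single-matrix fallback.
#' @param normalize set FALSE when the inputs are already logCPM.
#' @param seed integer seed covering every stochastic step.
#' @return A \linkS4class{TADCallSet}; metadata holds per-replicate R^2,
#'   the fit history, the candidate list and the run configuration.
#' @examples
#' cfg <- simConfig(m = 120L, k = 5L)
#' tr <- generateHierarchy(cfg, seed = 7)
#' sim <- sampleReplicates(tr, cfg, seed = 8)
#' calls <- fitHierarchicalTads(sim$replicates, seed = 9)
#' significantTads(calls)
#' @export
fitHierarchicalTads <- function(reps, boundaries = NULL, w = 5L,
                                filterAlpha = 0.05, minSize = 2L,
                                maxSize = Inf, maxSizeBp = NULL,
                                alpha = 0.03, beta = 1, l1 = 3,
                                epochs = 2L, cutoff = 0.05, tau = 0,
                                nBoot = 19L, normalize = TRUE, seed = 1L) {
  if (is(reps, "ContactMatrix")) reps <- ReplicateSet(list(reps))
  if (is.list(reps)) reps <- ReplicateSet(reps)
  stopifnot(is(reps, "ReplicateSet"))
  k <- nReplicates(reps)
  m <- binCount(reps)
  res <- hicResolution(reps[[1L]])
  if (!is.null(maxSizeBp)) {
    if (res <= 0L) stop("maxSizeBp requires a positive matrix resolution")
    maxSize <- maxSizeBp / res
  }
  norm <- lapply(seq_len(k), function(r) {
    x <- reps[[r]]
    if (!normalize) return(x)
    if (normState(x) != "raw") stop("normalize = TRUE expects raw matrices")
    logCPM(iceNormalize(x))
  })
  pseudo <- pseudoMatrix(norm)
  if (is.null(boundaries)) {
    boundaries <- callBoundaries(pseudo, w = w, filterAlpha = filterAlpha)
  }
  boundaries <- .checkBoundaries(boundaries, m)
  candidates <- assembleCandidates(boundaries, m, minSize = minSize,
                                   maxSize = maxSize)
  Y <- vapply(norm, buildResponse, numeric(m * (m + 1) / 2))
  fit <- fitFTRL(Y, candidates, m, alpha = alpha, beta = beta, l1 = l1,
                 epochs = epochs)
  # per-replicate fits run k x epochs passes so each replicate's estimate
  # carries the same total exposure as the joint fit (with identical
  # replicates this makes each of them reproduce the joint coefficients)
  perRep <- if (k >= 2L) {
    perReplicateFits(Y, fit$candidates, m, alpha = alpha, beta = beta,
                     l1 = l1, epochs = epochs * k)
  } else {
    bootstrapCoefficients(Y[, 1L], fit$candidates, m, nBoot = nBoot,
                          seed = seed, alpha = alpha, beta = beta,
                          l1 = l1, epochs = epochs)
  }
  config <- list(w = w, filterAlpha = filterAlpha, minSize = minSize,
                 maxSize = maxSize, alpha = alpha, beta = beta, l1 = l1,
                 epochs = epochs, cutoff = cutoff, tau = tau,
                 nBoot = nBoot, seed = seed, k = k, m = m,
                 resolution = res)
  callTads(fit$candidates, fit$coefficients, perRep, boundaries, m,
           cutoff = cutoff, tau = tau, seed = seed,
           metadata = list(r2 = fit$r2, history = fit$history,
                           candidates = fit$candidates, config = config,
                           chrom = chromName(reps[[1L]])))
}
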