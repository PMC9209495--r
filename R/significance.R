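#' Screen regression coefficients
#'
#' Keeps candidates whose coefficient strictly exceeds the threshold
#' tau; with the default tau = 0, the L1 sparsity of the solver has
#' already zeroed most coefficients.
#'
#' @param b nonnegative coefficient vector.
#' @param tau screening threshold.
#' @return Integer index set of surviving candidates.
#' @export
screenCoefficients <- function(b, tau = 0) {
  which(b > tau)
}

#' Right-tailed two-sample permutation p-value against zero
#'
#' Tests whether the k observed per-replicate coefficients of a
#' candidate TAD are significantly larger than zero: a two-sample
#' permutation test of the observed values against k zeros on the
#' difference of means. All C(2k, k) group assignments are enumerated
#' exactly when that count is <= \code{maxExact}; otherwise a seeded
#' Monte-Carlo approximation with \code{nPerm} draws is used (the
#' observed assignment is always included, so p is in (0, 1]).
#'
#' @param coeffs numeric vector of k per-replicate coefficients.
#' @param nPerm Monte-Carlo permutation count.
#' @param maxExact largest enumeration size for the exact test.
#' @param seed seed for the Monte-Carlo branch.
#' @return p-value in (0, 1].
#' @export
permPValueRight <- function(coeffs, nPerm = 10000L, maxExact = 20000L,
                            seed = NULL) {
  k <- length(coeffs)
  if (k < 1L) stop("need at least one coefficient")
  pool <- c(coeffs, rep(0, k))
  obs <- mean(coeffs) - 0
  tolEq <- 1e-12 * max(1, max(abs(pool)))
  nTotal <- choose(2L * k, k)
  statOf <- function(sel) mean(pool[sel]) - mean(pool[-sel])
  if (nTotal <= maxExact) {
    sel <- utils::combn(2L * k, k)
    stats <- apply(sel, 2L, statOf)
    sum(stats >= obs - tolEq) / nTotal
  } else {
    hits <- withSeed(seed, {
      sum(vapply(seq_len(nPerm), function(p) {
        statOf(sample.int(2L * k, k)) >= obs - tolEq
      }, logical(1)))
    })
    (hits + 1) / (nPerm + 1)
  }
}

#' Per-replicate coefficient fits
#'
#' Fits the candidate model independently on every replicate's response
#' (same candidates and hyperparameters); the resulting coefficient
#' samples feed the permutation test.
#'
#' @param responses npairs x k response matrix.
#' @param candidates candidate data.frame.
#' @param m bin count.
#' @param ... further arguments to \code{\link{fitFTRL}}.
#' @return Numeric matrix (candidates x replicates), candidate rows in
#'   (start, end) order.
#' @export
perReplicateFits <- function(responses, candidates, m, ...) {
  Y <- as.matrix(responses)
  vapply(seq_len(ncol(Y)), function(r) {
    fitFTRL(Y[, r], candidates, m, ...)$coefficients
  }, numeric(nrow(candidates)))
}

#' Bootstrap coefficient replicates for a single matrix
#'
#' With a single input matrix there are no replicate fits to feed the
#' permutation test; instead the (design row, response) observations are
#' resampled with replacement within each bin-distance stratum, and the
#' model is refitted on every resampled stream.
#'
#' @param response response vector of one matrix.
#' @param candidates candidate data.frame.
#' @param m bin count.
#' @param nBoot number of resamples (19 minimum).
#' @param seed integer seed.
#' @param ... further arguments to \code{\link{fitFTRL}}.
#' @return Numeric matrix (candidates x nBoot).
#' @export
bootstrapCoefficients <- function(response, candidates, m, nBoot = 19L,
                                  seed = NULL, ...) {
  nBoot <- max(19L, as.integer(nBoot))
  idx <- pairIndices(m)
  strata <- split(seq_len(nrow(idx)) - 1L, idx$d)
  withSeed(seed, {
    vapply(seq_len(nBoot), function(bt) {
      ord <- unlist(lapply(strata, function(s) {
        if (length(s) == 1L) s else sample(s, length(s), replace = TRUE)
      }), use.names = FALSE)
      fitFTRL(response, candidates, m, rowOrder = ord, ...)$coefficients
    }, numeric(nrow(candidates)))
  })
}

#' Call significant hierarchical TADs
#'
#' Candidates surviving the coefficient screen receive a right-tailed
#' permutation p-value from their per-replicate coefficients; those with
#' p below the cutoff are the final significant hierarchical TADs.
#' Boundary levels (number of significant calls sharing a boundary) and
#' partial-overlap flags are attached.
#'
#' @param candidates candidate data.frame ((start, end)-sorted).
#' @param coefficients joint-fit coefficient vector (aligned).
#' @param perRepCoeffs matrix (candidates x replicates) of
#'   per-replicate coefficients.
#' @param boundaries boundary cut positions used to assemble candidates.
#' @param m bin count.
#' @param cutoff significance cutoff on the p-value (default 0.05).
#' @param tau screening threshold on the joint coefficients.
#' @param seed seed for Monte-Carlo p-values (large k only).
#' @param metadata list stored on the result.
#' @return A \linkS4class{TADCallSet}.
#' @export
callTads <- function(candidates, coefficients, perRepCoeffs, boundaries,
                     m, cutoff = 0.05, tau = 0, seed = NULL,
                     metadata = list()) {
  stopifnot(length(coefficients) == nrow(candidates),
            nrow(perRepCoeffs) == nrow(candidates))
  # keep coefficients aligned while normalizing the candidate order
  ordC <- order(candidates$start, candidates$end)
  candidates <- .checkCandidates(candidates[ordC, ], m)
  coefficients <- coefficients[ordC]
  perRepCoeffs <- perRepCoeffs[ordC, , drop = FALSE]
  surv <- screenCoefficients(coefficients, tau)
  calls <- data.frame(
    start = candidates$start[surv], end = candidates$end[surv],
    coefficient = unname(coefficients[surv]))
  perRep <- perRepCoeffs[surv, , drop = FALSE]
  calls$p_value <- vapply(seq_along(surv), function(r) {
    permPValueRight(perRep[r, ], seed = seed)
  }, numeric(1))
  calls$significant <- calls$p_value < cutoff
  ord <- order(calls$start, calls$end)
  calls <- calls[ord, ]
  perRep <- perRep[ord, , drop = FALSE]
  rownames(calls) <- NULL
  sig <- calls[calls$significant, , drop = FALSE]
  lev <- boundaryLevels(sig)
  levOf <- function(pos) {
    out <- lev$level[match(pos, lev$position)]
    out[is.na(out)] <- 0L
    out
  }
  calls$level_start <- levOf(calls$start)
  calls$level_end <- levOf(calls$end)
  calls$pop_flag <- FALSE
  calls$pop_flag[calls$significant] <- classifyPartialOverlap(sig)
  new("TADCallSet", calls = calls, perReplicate = perRep,
      boundaries = .checkBoundaries(boundaries, m), m = as.integer(m),
      metadata = metadata)
}

#' @rdname TADCallSet-class
#' @param x a \linkS4class{TADCallSet}.
setMethod("tadCalls", "TADCallSet", function(x) x@calls)

#' @rdname TADCallSet-class
setMethod("significantTads", "TADCallSet", function(x) {
  x@calls[x@calls$significant, , drop = FALSE]
})

setMethod("show", "TADCallSet", function(object) {
  cat("TADCallSet:", nrow(object@calls), "screened candidates,",
      sum(object@calls$significant), "significant TADs on",
      object@m, "bins\n")
  if (!is.null(object@metadata$r2)) {
    cat("  fit R^2 per replicate:",
        paste(round(object@metadata$r2, 3), collapse = " "), "\n")
  }
})

#' Comprehensive values per basic TAD block
#'
#' A basic TAD block is the chromatin region between two adjacent
#' boundaries; its comprehensive value (CV) accumulates the coefficients
#' of all significant calls covering the block.
#'
#' @param calls a \linkS4class{TADCallSet} or data.frame of significant
#'   calls (start, end, coefficient).
#' @param boundaries boundary cut positions (taken from the call set if
#'   missing).
#' @return data.frame with columns block_start, block_end, cv.
#' @export
comprehensiveValues <- function(calls, boundaries = NULL) {
  if (is(calls, "TADCallSet")) {
    if (is.null(boundaries)) boundaries <- calls@boundaries
    calls <- significantTads(calls)
  }
  if (is.null(boundaries)) stop("boundaries required")
  b <- sort(unique(as.integer(boundaries)))
  blocks <- data.frame(block_start = b[-length(b)], block_end = b[-1L])
  blocks$cv <- vapply(seq_len(nrow(blocks)), function(r) {
    covering <- calls$start <= blocks$block_start[r] &
      calls$end >= blocks$block_end[r]
    sum(calls$coefficient[covering])
  }, numeric(1))
  blocks
}

#' Boundary hierarchy levels
#'
#' The level of a TAD boundary is the number of significant calls having
#' it as a start or end: first-level boundaries belong to a single TAD,
#' second- and third-level boundaries are shared by two and three
#' hierarchical TADs.
#'
#' @param calls a \linkS4class{TADCallSet} or data.frame of significant
#'   calls.
#' @return data.frame (position, level) for boundaries used by at least
#'   one call.
#' @export
boundaryLevels <- function(calls) {
  if (is(calls, "TADCallSet")) calls <- significantTads(calls)
  pos <- c(calls$start, calls$end)
  if (length(pos) == 0L) {
    return(data.frame(position = integer(0), level = integer(0)))
  }
  tab <- table(pos)
  data.frame(position = as.integer(names(tab)),
             level = as.integer(tab))
}

#' Flag partially overlapping TAD calls
#'
#' Two calls partially overlap iff their bin sets intersect and neither
#' contains the other; every call participating in at least one such
#' pair is flagged.
#'
#' @param calls a \linkS4class{TADCallSet} or data.frame with start, end.
#' @return Logical vector, one flag per call.
#' @export
classifyPartialOverlap <- function(calls) {
  if (is(calls, "TADCallSet")) calls <- significantTads(calls)
  n <- nrow(calls)
  flag <- logical(n)
  if (n < 2L) return(flag)
  s <- calls$start
  e <- calls$end
  for (a in seq_len(n - 1L)) {
    for (b in (a + 1L):n) {
      inter <- min(e[a], e[b]) - max(s[a], s[b])
      if (inter <= 0) next
      aInB <- s[b] <= s[a] && e[a] <= e[b]
      bInA <- s[a] <= s[b] && e[b] <= e[a]
      if (!aInB && !bInA) {
        flag[a] <- TRUE
        flag[b] <- TRUE
      }
    }
  }
  flag
}

#' Export TAD calls as BED-like TSV
#'
#' Columns: chrom, start, end, coefficient, p_value, level_start,
#' level_end, pop_flag. Coordinates in base pairs when
#' \code{resolution > 0}, otherwise bins. Only significant calls are
#' written unless \code{significantOnly = FALSE}.
#'
#' @param calls a \linkS4class{TADCallSet}.
#' @param path output path.
#' @param resolution base pairs per bin.
#' @param chrom chromosome label.
#' @param significantOnly write only significant calls.
#' @export
writeTadCalls <- function(calls, path, resolution = 0L, chrom = "chrS",
                          significantOnly = TRUE) {
  stopifnot(is(calls, "TADCallSet"))
  df <- if (significantOnly) significantTads(calls) else tadCalls(calls)
  scale <- if (resolution > 0L) resolution else 1L
  out <- data.frame(chrom = rep(chrom, nrow(df)), start = df$start * scale,
                    end = df$end * scale,
                    coefficient = signif(df$coefficient, 6L),
                    p_value = signif(df$p_value, 6L),
                    level_start = df$level_start,
                    level_end = df$level_end,
                    pop_flag = as.integer(df$pop_flag))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
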