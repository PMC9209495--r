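# run expr with a locally seeded RNG, restoring global state afterwards
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' ICE matrix balancing
#'
#' Iterative correction makes all (unmasked) bins of the contact matrix
#' equally visible: the matrix is repeatedly divided by the outer product
#' of its row-sum biases until the bias vector stabilizes. Bins with zero
#' coverage, or coverage below the \code{maskQuantile} quantile of row
#' sums, are masked out (set to zero) before balancing. The balanced
#' matrix is rescaled so its total mass equals the input total.
#'
#' @param x a raw \linkS4class{ContactMatrix}.
#' @param maxIter maximum number of balancing iterations.
#' @param tol convergence tolerance on the maximum relative change of the
#'   bias vector per iteration.
#' @param maskQuantile coverage quantile below which bins are masked.
#' @return An "iced" \linkS4class{ContactMatrix}; metadata records
#'   \code{ice_converged}, \code{ice_iterations} and \code{ice_masked}
#'   (0-based masked bin indices). A warning is raised (and the last
#'   iterate returned) if \code{maxIter} is reached without convergence.
#' @export
iceNormalize <- function(x, maxIter = 200L, tol = 1e-5,
                         maskQuantile = 0.02) {
  stopifnot(is(x, "ContactMatrix"))
  if (normState(x) != "raw") stop("iceNormalize expects a raw matrix")
  v <- cmValues(x)
  m <- nrow(v)
  rs <- rowSums(v)
  cutoff <- stats::quantile(rs, maskQuantile, names = FALSE)
  mask <- rs == 0 | rs < cutoff
  if (all(mask)) stop("all bins masked; nothing to balance")
  w <- v
  w[mask, ] <- 0
  w[, mask] <- 0
  converged <- FALSE
  iter <- 0L
  while (iter < maxIter) {
    iter <- iter + 1L
    s <- rowSums(w)
    sbar <- mean(s[!mask])
    if (sbar == 0) stop("unmasked rows have zero coverage")
    # square-root damped symmetric update: each iteration splits the
    # row-sum ratio evenly between the row and column bias, which
    # avoids the oscillation of the undamped outer-product correction
    delta <- sqrt(s / sbar)
    delta[mask] <- 1
    w <- w / outer(delta, delta)
    w[mask, ] <- 0
    w[, mask] <- 0
    if (max(abs(delta - 1)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("ICE did not converge within ", maxIter,
            " iterations; returning last iterate")
  }
  # conserve total matrix mass
  tot <- sum(w)
  if (tot > 0) w <- w * (sum(v) / tot)
  w <- (w + t(w)) / 2
  meta <- cmMetadata(x)
  meta$ice_converged <- converged
  meta$ice_iterations <- iter
  meta$ice_masked <- which(mask) - 1L
  .updateCM(x, w, normState = "iced", metadata = meta)
}

#' logCPM transformation
#'
#' Adjusts replicates to a common library scale:
#' \deqn{O_{ij} = \log_{10}(I_{ij} / L \times 10^6 + s)}
#' where the library size L is the sum of the strictly lower triangle,
#' including the diagonal by default, and the offset s >= 1 keeps the
#' output nonnegative.
#'
#' @param x a raw or iced \linkS4class{ContactMatrix}.
#' @param s additive offset inside the log (default 1).
#' @param includeDiagonal include the diagonal in the library size L.
#' @return A "logcpm" \linkS4class{ContactMatrix}.
#' @export
logCPM <- function(x, s = 1, includeDiagonal = TRUE) {
  stopifnot(is(x, "ContactMatrix"))
  if (normState(x) == "logcpm") stop("matrix is already logCPM-transformed")
  if (s < 1) stop("offset s must be >= 1 to keep the output nonnegative")
  v <- cmValues(x)
  L <- sum(v[lower.tri(v, diag = includeDiagonal)])
  if (L == 0) stop("degenerate input: library size L is zero")
  o <- log10(v / L * 1e6 + s)
  meta <- cmMetadata(x)
  meta$logcpm_library_size <- L
  .updateCM(x, o, normState = "logcpm", metadata = meta)
}

#' Pseudo contact matrix across replicates
#'
#' Element-wise geometric mean of the replicate matrices; any zero entry
#' in any replicate yields a zero pseudo entry. Replicates must share a
#' normalization state. The pseudo matrix serves consensus boundary
#' calling.
#'
#' @param reps a \linkS4class{ReplicateSet} or list of
#'   \linkS4class{ContactMatrix} objects.
#' @return A \linkS4class{ContactMatrix}.
#' @export
pseudoMatrix <- function(reps) {
  if (is.list(reps)) reps <- ReplicateSet(reps)
  stopifnot(is(reps, "ReplicateSet"))
  k <- nReplicates(reps)
  acc <- Reduce(`+`, lapply(seq_len(k), function(i) {
    suppressWarnings(log(cmValues(reps[[i]])))  # log(0) = -Inf -> pseudo 0
  }))
  g <- exp(acc / k)
  g[!is.finite(g)] <- 0
  ref <- reps[[1L]]
  .updateCM(ref, g, metadata = c(cmMetadata(ref), list(pseudo_of = k)))
}

#' Down-sample a raw contact matrix
#'
#' Emulates a lower sequencing depth: the nonzero lower-triangle (and
#' diagonal) counts are viewed as a multiset of N individual pairwise
#' interactions, floor(fraction * N) of which are drawn uniformly without
#' replacement and re-binned (a multivariate hypergeometric draw per
#' cell). The result total equals floor(fraction * N) exactly.
#'
#' @param x a raw \linkS4class{ContactMatrix} with integer counts.
#' @param fraction sampling fraction in (0, 1].
#' @param seed integer seed recorded in the output metadata.
#' @return A raw \linkS4class{ContactMatrix}.
#' @export
downsampleMatrix <- function(x, fraction, seed = NULL) {
  stopifnot(is(x, "ContactMatrix"))
  if (normState(x) != "raw") stop("downsampling requires raw counts")
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  v <- cmValues(x)
  if (max(abs(v - round(v))) > 1e-9) {
    stop("downsampling requires integer counts")
  }
  lowIdx <- which(lower.tri(v, diag = TRUE) & v > 0, arr.ind = TRUE)
  counts <- round(v[lowIdx])
  N <- sum(counts)
  nDraw <- floor(fraction * N)
  drawn <- withSeed(seed, {
    left <- nDraw
    remaining <- N
    out <- numeric(length(counts))
    for (c in seq_along(counts)) {
      if (left == 0L) break
      d <- stats::rhyper(1L, counts[c], remaining - counts[c], left)
      out[c] <- d
      left <- left - d
      remaining <- remaining - counts[c]
    }
    out
  })
  w <- matrix(0, nrow(v), ncol(v))
  w[lowIdx] <- drawn
  w <- w + t(w)
  diag(w) <- diag(w) / 2
  meta <- cmMetadata(x)
  meta$downsample_fraction <- fraction
  meta$downsample_seed <- seed
  .updateCM(x, w, metadata = meta)
}
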