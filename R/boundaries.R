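#' Diamond insulation signal
#'
#' For every cut position b (between bin b-1 and bin b, 0-based) the
#' signal is the mean of the w x w submatrix spanning rows [b-w, b) and
#' columns [b, b+w), truncated at the matrix edges. Low values mark
#' insulated positions (TAD boundaries).
#'
#' @param x a \linkS4class{ContactMatrix} (normalized recommended).
#' @param w window size in bins.
#' @return Numeric vector of length m; position b = 0 (no upstream rows)
#'   is NA.
#' @export
diamondSignal <- function(x, w = 5L) {
  stopifnot(is(x, "ContactMatrix"))
  v <- cmValues(x)
  m <- nrow(v)
  if (w <= 0L) stop("window w must be positive")
  if (w >= m / 2) stop("window w must be < m/2")
  sig <- rep(NA_real_, m)
  for (b in seq_len(m - 1L)) {  # cut position b, 1..m-1
    rows <- max(1L, b - w + 1L):b
    cols <- (b + 1L):min(m, b + w)
    sig[b + 1L] <- mean(v[rows, cols, drop = FALSE])
  }
  # store positions 0..m-1 at indices 1..m
  sig <- c(NA_real_, sig[2:m])
  sig
}

.runningMean <- function(x, width = 3L) {
  if (width <= 1L) return(x)
  half <- (width - 1L) %/% 2L
  n <- length(x)
  out <- x
  for (t in seq_len(n)) {
    lo <- max(1L, t - half)
    hi <- min(n, t + half)
    out[t] <- mean(x[lo:hi], na.rm = TRUE)
  }
  out
}

#' Call TAD boundaries by diamond insulation
#'
#' Local minima of the (lightly smoothed) diamond signal become boundary
#' candidates; each candidate is kept if a one-sided rank-sum test finds
#' the between-domain diamond values significantly lower than the
#' flanking within-domain values at \code{filterAlpha}. Chromosome start
#' (0) and end (m) are always included. Deterministic for fixed input.
#'
#' @param x a normalized \linkS4class{ContactMatrix} (iced or logcpm
#'   recommended).
#' @param w diamond window in bins.
#' @param filterAlpha significance level of the rank-sum filter.
#' @param smoothWidth running-mean width applied before minima detection.
#' @return Sorted integer vector of boundary cut positions in [0, m].
#' @export
callBoundaries <- function(x, w = 5L, filterAlpha = 0.05, smoothWidth = 3L) {
  stopifnot(is(x, "ContactMatrix"))
  v <- cmValues(x)
  m <- nrow(v)
  if (m < 2L * w + 1L) stop("matrix smaller than 2w + 1 bins")
  sig <- diamondSignal(x, w)
  sm <- .runningMean(sig, smoothWidth)
  keep <- integer(0)
  for (b in 2:(m - 1L)) {      # interior cut positions 2..m-1 (0-based)
    s0 <- sm[b + 1L]
    left <- sm[b]
    right <- if (b + 2L <= m) sm[b + 2L] else Inf
    # leftmost point of a plateau counts as the minimum
    if (is.na(s0) || is.na(left)) next
    if (!(s0 < left && s0 <= right)) next
    rows <- max(1L, b - w + 1L):b
    cols <- (b + 1L):min(m, b + w)
    diamond <- as.vector(v[rows, cols, drop = FALSE])
    upTri <- v[rows, rows, drop = FALSE]
    downTri <- v[cols, cols, drop = FALSE]
    within <- c(upTri[upper.tri(upTri)], downTri[upper.tri(downTri)])
    if (length(within) < 1L) next
    p <- suppressWarnings(
      stats::wilcox.test(diamond, within, alternative = "less",
                         exact = FALSE)$p.value)
    if (!is.na(p) && p < filterAlpha) keep <- c(keep, b)
  }
  sort(unique(c(0L, keep, m)))
}

# validate a boundary set against a bin count
.checkBoundaries <- function(b, m) {
  b <- as.integer(b)
  if (any(is.na(b)) || any(b < 0L | b > m)) {
    stop("boundaries must lie in [0, m]")
  }
  b <- sort(unique(c(0L, b, m)))
  if (length(b) < 2L) stop("need at least 2 boundaries")
  b
}

#' Assemble all-pairs candidate hierarchical TADs
#'
#' Every pair of boundaries (b_i, b_j), i < j, defines one candidate TAD
#' covering bins [b_i, b_j). Without size screening the candidate count
#' is choose(|B|, 2); an optional size window screens the list.
#' Candidates are indexed deterministically in (start, end) order.
#'
#' @param boundaries integer vector of boundary cut positions.
#' @param m bin count (defaults to \code{max(boundaries)}).
#' @param minSize minimum TAD size in bins.
#' @param maxSize maximum TAD size in bins (Inf = no cap).
#' @return data.frame with columns index, start, end.
#' @export
assembleCandidates <- function(boundaries, m = max(boundaries),
                               minSize = 2L, maxSize = Inf) {
  if (minSize > maxSize) stop("minSize must be <= maxSize")
  b <- .checkBoundaries(boundaries, m)
  pairs <- utils::combn(b, 2L)
  df <- data.frame(start = pairs[1L, ], end = pairs[2L, ])
  df$size <- df$end - df$start
  df <- df[df$size >= minSize & df$size <= maxSize, c("start", "end")]
  df <- df[order(df$start, df$end), ]
  rownames(df) <- NULL
  cbind(index = seq_len(nrow(df)), df)
}

#' Read / write boundary positions as BED-like text
#'
#' Single-position records "chrom start end" where end = start (+1
#' resolution unit). Written in base pairs when \code{resolution > 0},
#' otherwise bins.
#'
#' @param path file path.
#' @param resolution base pairs per bin (0 = bins).
#' @param boundaries integer boundary cut positions.
#' @param chrom chromosome label.
#' @return \code{readBoundaries}: sorted integer vector of cut positions.
#' @export
readBoundaries <- function(path, resolution = 0L) {
  df <- utils::read.table(path, header = FALSE)
  scale <- if (resolution > 0L) resolution else 1L
  sort(unique(as.integer(round(as.numeric(df[[2L]]) / scale))))
}

#' @rdname readBoundaries
#' @export
writeBoundaries <- function(boundaries, path, resolution = 0L,
                            chrom = "chrS") {
  scale <- if (resolution > 0L) resolution else 1L
  df <- data.frame(chrom = chrom, start = boundaries * scale,
                   end = boundaries * scale)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
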