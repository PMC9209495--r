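# normalize a TAD set to a clean data.frame of half-open intervals
.asTadSet <- function(x) {
  if (is(x, "TADCallSet")) x <- significantTads(x)
  if (is(x, "GroundTruth")) x <- x@allTads
  stopifnot(is.data.frame(x), all(c("start", "end") %in% names(x)))
  x <- x[, c("start", "end")]
  if (any(x$start >= x$end)) stop("intervals must satisfy start < end")
  x <- x[!duplicated(x), , drop = FALSE]
  rownames(x) <- NULL
  x
}

#' Jaccard index of two TAD intervals
#'
#' Intersection over union (IoU) of two half-open intervals, counted in
#' bins (or base pairs, if the intervals are in bp).
#'
#' @param a,b numeric length-2 vectors (start, end), half-open.
#' @return IoU in [0, 1].
#' @export
jaccardPair <- function(a, b) {
  inter <- max(0, min(a[2L], b[2L]) - max(a[1L], b[1L]))
  union <- (a[2L] - a[1L]) + (b[2L] - b[1L]) - inter
  inter / union
}

# IoU matrix between two interval sets
.iouMatrix <- function(T, C) {
  outer(seq_len(nrow(T)), seq_len(nrow(C)), Vectorize(function(i, j) {
    jaccardPair(c(T$start[i], T$end[i]), c(C$start[j], C$end[j]))
  }))
}

#' Jaccard index between two TAD sets
#'
#' Each called TAD is scored by its best IoU against the other set; the
#' final index averages the mean best-match of C against T and the mean
#' best-match of T against C, and is therefore symmetric.
#'
#' @param T,C TAD sets: data.frames with start, end (half-open), or
#'   \linkS4class{TADCallSet} / \linkS4class{GroundTruth} objects.
#' @return Jaccard index in [0, 1]; 1 iff the sets are equal.
#' @export
jaccardSets <- function(T, C) {
  T <- .asTadSet(T)
  C <- .asTadSet(C)
  if (nrow(T) == 0L || nrow(C) == 0L) {
    stop("Jaccard index undefined for an empty TAD set")
  }
  iou <- .iouMatrix(T, C)
  (mean(apply(iou, 2L, max)) + mean(apply(iou, 1L, max))) / 2
}

#' Modified Jaccard index (lower vs higher resolution)
#'
#' Mean over the lower-resolution set A of the best IoU against the
#' higher-resolution set B; asymmetric by design, and exactly 1 whenever
#' A is a subset of B. Intervals are mapped to a common base-pair
#' coordinate system via the per-set resolutions before comparison.
#'
#' @param A TAD set called at the lower resolution.
#' @param B TAD set called at the higher resolution.
#' @param resA,resB base pairs per bin of each set (1 = already common).
#' @return Modified Jaccard index in [0, 1].
#' @export
modifiedJaccard <- function(A, B, resA = 1L, resB = 1L) {
  A <- .asTadSet(A)
  B <- .asTadSet(B)
  if (nrow(A) == 0L) stop("modified Jaccard undefined for empty A")
  if (nrow(B) == 0L) stop("modified Jaccard undefined for empty B")
  A$start <- A$start * resA; A$end <- A$end * resA
  B$start <- B$start * resB; B$end <- B$end * resB
  mean(apply(.iouMatrix(A, B), 1L, max))
}

#' F1 score between a ground-truth and a called TAD set
#'
#' A TAD in T and a TAD in C are the same when their IoU is strictly
#' larger than the threshold (default 90%). Matching is one-to-one
#' greedy by descending IoU (a many-to-one mode is exposed); precision =
#' matches / |C|, recall = matches / |T|, F1 their harmonic mean (0 when
#' both are 0).
#'
#' @param T ground-truth TAD set.
#' @param C called TAD set.
#' @param iouThreshold IoU match threshold (strict >).
#' @param matching "one-to-one" (greedy) or "many-to-one".
#' @return List with precision, recall, f1.
#' @export
f1Score <- function(T, C, iouThreshold = 0.9,
                    matching = c("one-to-one", "many-to-one")) {
  matching <- match.arg(matching)
  T <- .asTadSet(T)
  C <- .asTadSet(C)
  if (nrow(T) == 0L) stop("F1 undefined for empty ground truth")
  if (nrow(C) == 0L) {
    return(list(precision = 0, recall = 0, f1 = 0))
  }
  iou <- .iouMatrix(T, C)
  if (matching == "one-to-one") {
    matches <- 0L
    usedT <- logical(nrow(T))
    usedC <- logical(nrow(C))
    ord <- order(iou, decreasing = TRUE)
    for (o in ord) {
      if (iou[o] <= iouThreshold) break
      ti <- (o - 1L) %% nrow(T) + 1L
      cj <- (o - 1L) %/% nrow(T) + 1L
      if (usedT[ti] || usedC[cj]) next
      usedT[ti] <- TRUE
      usedC[cj] <- TRUE
      matches <- matches + 1L
    }
    precision <- matches / nrow(C)
    recall <- matches / nrow(T)
  } else {
    precision <- mean(apply(iou, 2L, max) > iouThreshold)
    recall <- mean(apply(iou, 1L, max) > iouThreshold)
  }
  f1 <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  list(precision = precision, recall = recall, f1 = f1)
}

#' Evaluate two TAD sets with all metrics
#'
#' @param T,C TAD sets (see \code{\link{jaccardSets}}).
#' @param iouThreshold F1 match threshold.
#' @return List with jaccard, modified_jaccard (T against C), precision,
#'   recall, f1 and the two set sizes.
#' @export
evaluateTadSets <- function(T, C, iouThreshold = 0.9) {
  f1 <- f1Score(T, C, iouThreshold)
  list(jaccard = jaccardSets(T, C),
       modified_jaccard = modifiedJaccard(T, C),
       precision = f1$precision, recall = f1$recall, f1 = f1$f1,
       n_truth = nrow(.asTadSet(T)), n_called = nrow(.asTadSet(C)))
}
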