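# Independent oracles used across tests. These deliberately avoid the
# package's own code paths (dense matrices, explicit bin sets, cyclic
# coordinate descent) so that agreement is evidence of correctness.

# dense design matrix of Eq-style model: one column per candidate TAD,
# value log(m/(d+1)) on rows (lower-triangle pairs) inside the candidate
denseDesign <- function(cand, m) {
  idx <- pairIndices(m)
  X <- matrix(0, nrow(idx), nrow(cand))
  for (c in seq_len(nrow(cand))) {
    inC <- idx$j >= cand$start[c] & idx$i < cand$end[c]
    X[inC, c] <- log(m / (idx$d[inC] + 1))
  }
  X
}

# high-precision batch nonnegative lasso by cyclic coordinate descent:
# min 0.5 * sum_r ||y_r - X b||^2 + lam * ||b||_1  s.t. b >= 0
nnlassoCD <- function(X, Y, lam, maxit = 50000L, tol = 1e-13) {
  Y <- as.matrix(Y)
  k <- ncol(Y)
  n <- ncol(X)
  b <- numeric(n)
  xs <- colSums(X^2) * k
  R <- Y - X %*% b   # residual per replicate
  for (it in seq_len(maxit)) {
    del <- 0
    for (c in seq_len(n)) {
      if (xs[c] == 0) next
      rho <- sum(X[, c] * rowSums(R)) + xs[c] * b[c]
      bn <- max(0, (rho - lam) / xs[c])
      if (bn != b[c]) {
        R <- R - X[, c] %o% rep(bn - b[c], k)
        del <- max(del, abs(bn - b[c]))
      }
      b[c] <- bn
    }
    if (del < tol) break
  }
  b
}

# explicit bin-set metrics (enumerate bins, no interval arithmetic)
binsOf <- function(iv) seq(iv[1] + 1L, iv[2])  # half-open -> 1-based bins

bruteJaccardPair <- function(a, b) {
  A <- binsOf(a); B <- binsOf(b)
  length(intersect(A, B)) / length(union(A, B))
}

bruteIouMatrix <- function(T, C) {
  outer(seq_len(nrow(T)), seq_len(nrow(C)), Vectorize(function(i, j) {
    bruteJaccardPair(c(T$start[i], T$end[i]), c(C$start[j], C$end[j]))
  }))
}

bruteJaccardSets <- function(T, C) {
  iou <- bruteIouMatrix(T, C)
  (mean(apply(iou, 2, max)) + mean(apply(iou, 1, max))) / 2
}

bruteModifiedJaccard <- function(A, B) {
  mean(apply(bruteIouMatrix(A, B), 1, max))
}

bruteF1 <- function(T, C, thr = 0.9) {
  iou <- bruteIouMatrix(T, C)
  matches <- 0L
  repeat {
    if (all(iou <= thr)) break
    o <- which(iou == max(iou), arr.ind = TRUE)[1, ]
    matches <- matches + 1L
    iou[o[1], ] <- -1
    iou[, o[2]] <- -1
  }
  p <- matches / nrow(C)
  r <- matches / nrow(T)
  list(precision = p, recall = r,
       f1 = if (p + r == 0) 0 else 2 * p * r / (p + r))
}

# random non-degenerate interval set on [0, m)
randomTadSet <- function(m = 30L, n = NULL) {
  if (is.null(n)) n <- sample(1:6, 1)
  df <- data.frame(start = sample(0:(m - 2L), n, replace = TRUE))
  df$end <- df$start + sample(1:8, n, replace = TRUE)
  df$end <- pmin(df$end, m)
  unique(df)
}

# a tiny well-posed regression instance: tiling of [0, m) into 4-7 bin
# base TADs plus one meta spanning two adjacent tiles
makeTinyInstance <- function(m = 20L) {
  sizes <- integer(0); left <- m
  while (left > 7L) {
    s <- sample(4:7, 1L)
    if (left - s < 4L && left - s > 0L) next
    sizes <- c(sizes, s); left <- left - s
  }
  if (left > 0L) sizes <- c(sizes, left)
  ends <- cumsum(sizes)
  cand <- data.frame(start = c(0L, ends[-length(ends)]), end = ends)
  i <- sample(seq_len(nrow(cand) - 1L), 1L)
  cand <- rbind(cand,
                data.frame(start = cand$start[i], end = cand$end[i + 1L]))
  cand <- cand[order(cand$start, cand$end), ]
  rownames(cand) <- NULL
  cand
}

# exact two-sample right-tailed permutation p by direct enumeration,
# written independently of the package implementation
brutePermP <- function(vals) {
  k <- length(vals)
  pool <- c(vals, rep(0, k))
  obs <- mean(vals)
  sel <- utils::combn(2L * k, k)
  stats <- apply(sel, 2, function(s) mean(pool[s]) - mean(pool[-s]))
  mean(stats >= obs - 1e-12)
}
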