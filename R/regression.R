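#' Lower-triangle pair indices of the response ordering
#'
#' The response vector enumerates the lower triangle plus diagonal in a
#' fixed row-major order (i = 0..m-1, j = 0..i); this order is part of
#' the model contract.
#'
#' @param m bin count.
#' @return data.frame with 0-based columns i, j and bin distance d.
#' @export
pairIndices <- function(m) {
  i <- rep.int(0:(m - 1L), 1:m)
  j <- sequence(1:m) - 1L
  data.frame(i = i, j = j, d = i - j)
}

#' Build the regression response from a normalized contact matrix
#'
#' @param x a "logcpm" \linkS4class{ContactMatrix} (the log scale is
#'   applied by the logCPM transform).
#' @return Numeric vector of length m(m+1)/2 in the canonical
#'   lower-triangle order.
#' @export
buildResponse <- function(x) {
  stopifnot(is(x, "ContactMatrix"))
  if (normState(x) != "logcpm") {
    stop("response requires a logCPM-normalized matrix; run logCPM() first")
  }
  v <- cmValues(x)
  idx <- pairIndices(nrow(v))
  v[cbind(idx$i + 1L, idx$j + 1L)]
}

#' Design value of a bin pair at distance d
#'
#' Every candidate TAD containing a pair contributes
#' \code{log(m / (d + 1))} (natural log by default) to the fitted value;
#' the value is 0 at the maximal distance d = m - 1 and decreases
#' monotonically with d.
#'
#' @param d bin distance(s), 0 <= d <= m - 1.
#' @param m bin count.
#' @param logBase base of the logarithm (default natural).
#' @return Numeric design value(s).
#' @export
designValue <- function(d, m, logBase = exp(1)) {
  if (any(d < 0)) stop("bin distance d must be >= 0")
  if (any(d > m - 1)) stop("bin distance d must be <= m - 1")
  log(m / (d + 1)) / log(logBase)
}

# design values for all distances 0..m-1
.designByDistance <- function(m, logBase = exp(1)) {
  designValue(0:(m - 1L), m, logBase)
}

.checkCandidates <- function(candidates, m) {
  stopifnot(is.data.frame(candidates),
            all(c("start", "end") %in% names(candidates)))
  if (nrow(candidates) == 0L) stop("empty candidate list")
  if (any(candidates$start >= candidates$end) ||
      any(candidates$start < 0L) || any(candidates$end > m)) {
    stop("candidate intervals must satisfy 0 <= start < end <= m")
  }
  candidates <- candidates[order(candidates$start, candidates$end), ]
  rownames(candidates) <- NULL
  candidates
}

#' Fit nonnegative sparse TAD coefficients with FTRL-Proximal
#'
#' Streams the (design row, response) observations replicate-major for
#' \code{epochs} passes through an FTRL-Proximal learner with quadratic
#' loss, per-coordinate adaptive learning rates alpha/(beta + sqrt(n)),
#' L1 soft-thresholding at \code{l1} and nonnegativity clamping of each
#' closed-form weight. The full design matrix is never materialized: a
#' row's nonzero coordinates are recomputed from the candidate intervals
#' on the fly.
#'
#' @param responses numeric vector (single matrix) or npairs x k matrix
#'   of per-replicate responses from \code{\link{buildResponse}}.
#' @param candidates data.frame with columns start, end (bin cut
#'   positions) from \code{\link{assembleCandidates}}.
#' @param m bin count.
#' @param alpha learning-rate scale.
#' @param beta learning-rate offset (fixed at 1 in practice).
#' @param l1 L1 regularization strength.
#' @param epochs passes over the data (>= 1).
#' @param shuffle optionally shuffle the row stream each epoch.
#' @param seed seed for the optional shuffle.
#' @param logBase design-value log base.
#' @param rowOrder optional explicit 0-based row stream of one pass
#'   (used by the bootstrap fallback); overrides \code{shuffle}.
#' @return List with \code{coefficients} (named by candidate index,
#'   aligned with the (start, end)-sorted candidate order), \code{r2}
#'   (final per-replicate R^2), \code{history} (data.frame epoch x
#'   replicate R^2 log) and \code{candidates}.
#' @export
fitFTRL <- function(responses, candidates, m, alpha = 0.03, beta = 1,
                    l1 = 3, epochs = 2L, shuffle = FALSE, seed = NULL,
                    logBase = exp(1), rowOrder = NULL) {
  if (epochs < 1L) stop("epochs must be >= 1")
  if (alpha <= 0 || l1 < 0) stop("alpha must be > 0 and l1 >= 0")
  Y <- as.matrix(responses)
  npairs <- m * (m + 1) / 2
  if (nrow(Y) != npairs) {
    stop("response length ", nrow(Y), " != m(m+1)/2 = ", npairs)
  }
  bad <- which(!is.finite(Y), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("non-finite response at row ", bad[1L, 1L],
         ", replicate ", bad[1L, 2L])
  }
  candidates <- .checkCandidates(candidates, m)
  xd <- .designByDistance(m, logBase)
  if (is.null(rowOrder)) {
    rowOrder <- if (isTRUE(shuffle)) {
      # one independent permutation per epoch
      withSeed(seed, vapply(seq_len(epochs),
                            function(e) sample.int(npairs) - 1L,
                            integer(npairs)))
    } else {
      matrix(0:(npairs - 1L), ncol = 1L)
    }
  } else {
    rowOrder <- as.matrix(rowOrder)
    storage.mode(rowOrder) <- "integer"
    if (any(rowOrder < 0L | rowOrder >= npairs)) {
      stop("rowOrder indices out of range")
    }
  }
  fit <- ftrl_fit_cpp(Y, as.integer(candidates$start),
                      as.integer(candidates$end), as.integer(m), xd,
                      alpha, beta, l1, as.integer(epochs), rowOrder)
  r2h <- fit$r2_history
  history <- data.frame(
    epoch = rep(seq_len(nrow(r2h)), ncol(r2h)),
    replicate = rep(seq_len(ncol(r2h)), each = nrow(r2h)),
    r2 = as.vector(r2h))
  list(coefficients = stats::setNames(fit$coefficients,
                                      candidates$index %||% seq_len(nrow(candidates))),
       r2 = r2h[nrow(r2h), ],
       history = history,
       candidates = candidates)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fitted contact matrix from TAD coefficients
#'
#' Re-bins the fitted values y_hat = X b into a symmetric matrix in the
#' canonical response ordering.
#'
#' @param coefficients numeric vector of candidate coefficients.
#' @param candidates matching candidate data.frame (start, end).
#' @param m bin count.
#' @param logBase design-value log base.
#' @return A \linkS4class{ContactMatrix} with normState "logcpm" (the
#'   response scale).
#' @export
fittedMatrix <- function(coefficients, candidates, m, logBase = exp(1)) {
  candidates <- .checkCandidates(candidates, m)
  if (length(coefficients) != nrow(candidates)) {
    stop("coefficient length must match candidate count")
  }
  yhat <- ftrl_predict_cpp(as.numeric(coefficients),
                           as.integer(candidates$start),
                           as.integer(candidates$end), as.integer(m),
                           .designByDistance(m, logBase))
  idx <- pairIndices(m)
  v <- matrix(0, m, m)
  v[cbind(idx$i + 1L, idx$j + 1L)] <- yhat
  v[cbind(idx$j + 1L, idx$i + 1L)] <- yhat
  ContactMatrix(v, normState = "logcpm",
                metadata = list(fitted = TRUE))
}

#' Predicted response vector for given coefficients
#'
#' @inheritParams fittedMatrix
#' @return Numeric vector of length m(m+1)/2.
#' @export
predictResponse <- function(coefficients, candidates, m, logBase = exp(1)) {
  candidates <- .checkCandidates(candidates, m)
  ftrl_predict_cpp(as.numeric(coefficients),
                   as.integer(candidates$start),
                   as.integer(candidates$end), as.integer(m),
                   .designByDistance(m, logBase))
}

#' Coefficient of determination against a response
#'
#' @param y observed response vector.
#' @param yhat fitted response vector.
#' @return R^2 = 1 - SS_res / SS_tot (NA when SS_tot = 0).
#' @export
rSquared <- function(y, yhat) {
  sstot <- sum((y - mean(y))^2)
  if (sstot == 0) return(NA_real_)
  1 - sum((y - yhat)^2) / sstot
}
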