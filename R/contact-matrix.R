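#' Construct a ContactMatrix
#'
#' @param values numeric square symmetric nonnegative matrix.
#' @param resolution base pairs per bin; 0 for abstract bins.
#' @param chrom chromosome label.
#' @param normState normalization state: "raw", "iced" or "logcpm".
#' @param metadata free-form provenance list.
#' @return A \linkS4class{ContactMatrix}.
#' @examples
#' cm <- ContactMatrix(matrix(c(0, 5, 5, 0), 2))
#' binCount(cm)
#' @export
ContactMatrix <- function(values, resolution = 0L, chrom = "chrS",
                          normState = "raw", metadata = list()) {
  storage.mode(values) <- "double"
  dimnames(values) <- NULL
  new("ContactMatrix", values = values, resolution = as.integer(resolution),
      chrom = chrom, normState = normState, metadata = metadata)
}

#' @rdname ContactMatrix-class
#' @aliases cmValues,ContactMatrix-method
setMethod("cmValues", "ContactMatrix", function(x) x@values)

#' @rdname ContactMatrix-class
setMethod("binCount", "ContactMatrix", function(x) nrow(x@values))

#' @rdname ContactMatrix-class
setMethod("hicResolution", "ContactMatrix", function(x) x@resolution)

#' @rdname ContactMatrix-class
setMethod("chromName", "ContactMatrix", function(x) x@chrom)

#' @rdname ContactMatrix-class
setMethod("normState", "ContactMatrix", function(x) x@normState)

#' @rdname ContactMatrix-class
setMethod("cmMetadata", "ContactMatrix", function(x) x@metadata)

setMethod("show", "ContactMatrix", function(object) {
  cat("ContactMatrix:", object@chrom,
      sprintf("(%d x %d bins", nrow(object@values), ncol(object@values)),
      if (object@resolution > 0L) sprintf("@ %d bp)", object@resolution)
      else "abstract bins)",
      "\n  normalization:", object@normState,
      "\n  total counts:", format(sum(object@values)), "\n")
})

# internal: replace values, keep/patch the rest
.updateCM <- function(x, values, normState = x@normState,
                      metadata = x@metadata) {
  ContactMatrix(values, resolution = x@resolution, chrom = x@chrom,
                normState = normState, metadata = metadata)
}

#' Construct a ReplicateSet
#'
#' @param ... \linkS4class{ContactMatrix} objects, or a single list of them.
#' @return A \linkS4class{ReplicateSet}.
#' @export
ReplicateSet <- function(...) {
  mats <- list(...)
  if (length(mats) == 1L && is.list(mats[[1L]]) && !is(mats[[1L]], "ContactMatrix")) {
    mats <- mats[[1L]]
  }
  new("ReplicateSet", matrices = mats)
}

#' @rdname ReplicateSet-class
#' @param x a \linkS4class{ReplicateSet}.
setMethod("nReplicates", "ReplicateSet", function(x) length(x@matrices))

#' @rdname ReplicateSet-class
setMethod("binCount", "ReplicateSet", function(x) binCount(x@matrices[[1L]]))

#' @rdname ReplicateSet-class
setMethod("normState", "ReplicateSet", function(x) normState(x@matrices[[1L]]))

#' @export
setMethod("length", "ReplicateSet", function(x) length(x@matrices))

#' @export
setMethod("[[", "ReplicateSet", function(x, i) x@matrices[[i]])

setMethod("show", "ReplicateSet", function(object) {
  cat("ReplicateSet of", length(object@matrices), "contact matrices,",
      binCount(object), "bins,", normState(object), "\n")
})

#' Read a contact matrix from text
#'
#' Two plain-text dialects are supported: \code{dense} (m rows of m
#' whitespace-separated numbers) and \code{triplet} (lines of
#' \code{"bin_i bin_j count"} with 0-based bin indices; upper or lower
#' triangle accepted, duplicates summed, mirrored across the diagonal).
#'
#' @param path file path.
#' @param format "dense" or "triplet".
#' @param mHint bin count for triplet input (otherwise inferred as
#'   max index + 1).
#' @param resolution,chrom passed to \code{\link{ContactMatrix}}.
#' @return A \linkS4class{ContactMatrix} with \code{normState = "raw"}.
#' @export
readContactMatrix <- function(path, format = c("dense", "triplet"),
                              mHint = NULL, resolution = 0L, chrom = "chrS") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "dense") {
    rows <- utils::read.table(path, header = FALSE,
                              colClasses = "numeric")
    v <- as.matrix(rows)
    if (nrow(v) != ncol(v)) {
      stop("dense input is not square: ", nrow(v), " rows x ",
           ncol(v), " columns")
    }
    if (max(abs(v - t(v))) > 1e-6 * max(1, max(abs(v)))) {
      stop("dense input is not symmetric")
    }
    # symmetrize exactly to absorb text round-off
    v <- (v + t(v)) / 2
  } else {
    tr <- utils::read.table(path, header = FALSE)
    if (ncol(tr) != 3L) stop("triplet input must have 3 columns")
    bi <- as.integer(tr[[1L]]); bj <- as.integer(tr[[2L]])
    cnt <- as.numeric(tr[[3L]])
    if (any(cnt < 0)) stop("negative count in triplet input")
    if (any(bi < 0L | bj < 0L)) stop("negative bin index in triplet input")
    m <- if (is.null(mHint)) max(bi, bj) + 1L else as.integer(mHint)
    if (any(bi >= m | bj >= m)) {
      stop("triplet bin index >= m (", m, ")")
    }
    v <- matrix(0, m, m)
    for (r in seq_along(cnt)) {
      v[bi[r] + 1L, bj[r] + 1L] <- v[bi[r] + 1L, bj[r] + 1L] + cnt[r]
    }
    v <- v + t(v)
    diag(v) <- diag(v) / 2
  }
  ContactMatrix(v, resolution = resolution, chrom = chrom, normState = "raw")
}

#' Write a contact matrix to text
#'
#' Dense output is written with 6 significant digits; triplet output holds
#' the nonzero lower-triangle (incl. diagonal) entries as
#' \code{"i j count"} with 0-based indices.
#'
#' @param x a \linkS4class{ContactMatrix}.
#' @param path output file path.
#' @param format "dense" or "triplet".
#' @export
writeContactMatrix <- function(x, path, format = c("dense", "triplet")) {
  format <- match.arg(format)
  v <- cmValues(x)
  if (format == "dense") {
    txt <- apply(signif(v, 6L), 1L, paste, collapse = "\t")
    writeLines(txt, path)
  } else {
    keep <- which(lower.tri(v, diag = TRUE) & v != 0, arr.ind = TRUE)
    df <- data.frame(i = keep[, 1L] - 1L, j = keep[, 2L] - 1L,
                     count = signif(v[keep], 6L))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
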