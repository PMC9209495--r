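#' @import methods
NULL

.SYMMETRY_TOL <- 1e-9

#' ContactMatrix: a symmetric Hi-C contact matrix
#'
#' Container for a square, symmetric, nonnegative interaction-frequency
#' matrix at a fixed bin resolution, together with its normalization state.
#'
#' @slot values numeric m x m matrix of interaction frequencies.
#' @slot resolution integer, base pairs per bin; \code{0} means abstract
#'   (unitless) bins, as produced by the simulator.
#' @slot chrom character chromosome label.
#' @slot normState one of \code{"raw"}, \code{"iced"}, \code{"logcpm"}.
#' @slot metadata list of free-form provenance (seeds, convergence flags).
#'
#' @section Validity:
#' \code{values} must be square with at least 2 bins, finite, nonnegative
#' and symmetric to within 1e-9 (absolute, relative to the largest entry).
#'
#' @exportClass ContactMatrix
setClass("ContactMatrix",
  slots = c(
    values = "matrix",
    resolution = "integer",
    chrom = "character",
    normState = "character",
    metadata = "list"
  ),
  prototype = prototype(
    resolution = 0L, chrom = "chrS", normState = "raw", metadata = list()
  )
)

setValidity("ContactMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("'values' must be numeric")
  if (nrow(v) != ncol(v)) return("'values' must be square")
  if (nrow(v) < 2L) return("bin count m must be >= 2")
  if (any(!is.finite(v))) return("'values' must be finite")
  if (any(v < 0)) return("'values' must be nonnegative")
  tol <- .SYMMETRY_TOL * max(1, max(abs(v)))
  if (max(abs(v - t(v))) > tol) return("'values' must be symmetric")
  if (length(object@normState) != 1L ||
      !object@normState %in% c("raw", "iced", "logcpm")) {
    return("'normState' must be one of raw, iced, logcpm")
  }
  if (length(object@resolution) != 1L || object@resolution < 0L) {
    return("'resolution' must be a single nonnegative integer")
  }
  TRUE
})

#' ReplicateSet: an ordered set of contact-matrix replicates
#'
#' Holds k \linkS4class{ContactMatrix} objects sharing bin count,
#' resolution, chromosome and normalization state (the columns of the
#' multi-replicate response matrix Y).
#'
#' @slot matrices list of \linkS4class{ContactMatrix}.
#' @exportClass ReplicateSet
setClass("ReplicateSet", slots = c(matrices = "list"))

setValidity("ReplicateSet", function(object) {
  mats <- object@matrices
  if (length(mats) < 1L) return("at least one replicate required")
  if (!all(vapply(mats, is, logical(1), "ContactMatrix"))) {
    return("all elements must be ContactMatrix objects")
  }
  ref <- mats[[1L]]
  same <- vapply(mats, function(x) {
    nrow(x@values) == nrow(ref@values) &&
      x@resolution == ref@resolution &&
      identical(x@chrom, ref@chrom) &&
      identical(x@normState, ref@normState)
  }, logical(1))
  if (!all(same)) {
    return("replicates must share bin count, resolution, chrom and normState")
  }
  TRUE
})

#' SimulationConfig: parameters of the contact-matrix simulator
#'
#' Negative-binomial Hi-C simulation parameters. Interaction means decay
#' with bin distance d as K (d + prior)^decay; in-TAD signal uses
#' \code{Kt}, chromatin loops \code{Kd} (= 2 Kt by default), and sampled
#' noise positions receive a flat mean \code{Knoise}.
#'
#' @slot m integer bin count.
#' @slot Kt,Kd,Knoise numeric signal scales of the three components.
#' @slot decay numeric (negative) power-law decay exponent.
#' @slot prior numeric distance offset added before applying the decay.
#' @slot dispersion numeric NB dispersion; variance = mu + dispersion mu^2.
#' @slot loopFraction fraction of lower-triangle bin pairs made loops.
#' @slot noiseFraction per-replicate fraction of bin pairs made noise.
#' @slot popFraction fraction of base TADs spawning a partially
#'   overlapping meta-TAD couple.
#' @slot boundaryRemoval fraction of internal boundaries removed per layer.
#' @slot baseSizeMin,baseSizeMax base-TAD size range in bins.
#' @slot k integer replicate count.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  slots = c(
    m = "integer", Kt = "numeric", Kd = "numeric", Knoise = "numeric",
    decay = "numeric", prior = "numeric", dispersion = "numeric",
    loopFraction = "numeric", noiseFraction = "numeric",
    popFraction = "numeric", boundaryRemoval = "numeric",
    baseSizeMin = "integer", baseSizeMax = "integer", k = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  fr <- c(object@loopFraction, object@noiseFraction, object@popFraction,
          object@boundaryRemoval)
  if (any(fr < 0 | fr > 1)) return("fractions must lie in [0, 1]")
  if (object@dispersion < 0) return("dispersion must be >= 0")
  if (object@decay >= 0) return("decay exponent must be negative")
  if (object@baseSizeMin < 2L || object@baseSizeMax < object@baseSizeMin) {
    return("invalid base-TAD size range")
  }
  if (object@m < 3L * object@baseSizeMin) {
    return("m too small to hold at least 3 base TADs")
  }
  if (object@k < 1L) return("k must be >= 1")
  TRUE
})

#' GroundTruth: layered TAD hierarchy from the simulator
#'
#' @slot layers list of three data.frames (start, end) of half-open bin
#'   intervals; layer 1 tiles the chromosome with base TADs.
#' @slot allTads data.frame (start, end, layer, pop) of distinct intervals.
#' @slot loops data.frame (i, j) of loop bin pairs (i >= j).
#' @slot noiseSets list (one per replicate) of data.frames (i, j) of
#'   noise bin pairs; filled by \code{\link{sampleReplicates}}.
#' @slot popTads data.frame of constructed partially overlapping
#'   meta-TAD pairs and the shared base TAD.
#' @slot m integer bin count.
#' @exportClass GroundTruth
setClass("GroundTruth",
  slots = c(
    layers = "list", allTads = "data.frame", loops = "data.frame",
    noiseSets = "list", popTads = "data.frame", m = "integer"
  )
)

#' TADCallSet: screened candidate TADs with significance calls
#'
#' @slot calls data.frame with columns start, end (boundary cut
#'   positions, half-open bin intervals), coefficient, p_value,
#'   significant, level_start, level_end, pop_flag.
#' @slot perReplicate numeric matrix (candidates surviving the screen x
#'   replicates) of per-replicate coefficients used by the permutation test.
#' @slot boundaries integer vector of boundary cut positions incl. 0 and m.
#' @slot m integer bin count.
#' @slot metadata list (R^2 per replicate, fit history, config).
#' @exportClass TADCallSet
setClass("TADCallSet",
  slots = c(
    calls = "data.frame", perReplicate = "matrix",
    boundaries = "integer", m = "integer", metadata = "list"
  )
)
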