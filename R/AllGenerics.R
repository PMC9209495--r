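#' @rdname ContactMatrix-class
#' @param x a \linkS4class{ContactMatrix} (or \linkS4class{ReplicateSet}).
#' @export
setGeneric("cmValues", function(x) standardGeneric("cmValues"))

#' @rdname ContactMatrix-class
#' @export
setGeneric("binCount", function(x) standardGeneric("binCount"))

#' @rdname ContactMatrix-class
#' @export
setGeneric("hicResolution", function(x) standardGeneric("hicResolution"))

#' @rdname ContactMatrix-class
#' @export
setGeneric("chromName", function(x) standardGeneric("chromName"))

#' @rdname ContactMatrix-class
#' @export
setGeneric("normState", function(x) standardGeneric("normState"))

#' @rdname ContactMatrix-class
#' @export
setGeneric("cmMetadata", function(x) standardGeneric("cmMetadata"))

#' @rdname ReplicateSet-class
#' @export
setGeneric("nReplicates", function(x) standardGeneric("nReplicates"))

#' @rdname TADCallSet-class
#' @export
setGeneric("tadCalls", function(x) standardGeneric("tadCalls"))

#' @rdname TADCallSet-class
#' @export
setGeneric("significantTads", function(x) standardGeneric("significantTads"))
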