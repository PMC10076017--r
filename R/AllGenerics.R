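#' @rdname variantTable
#' @export
setGeneric("variantTable", function(x, ...) standardGeneric("variantTable"))

#' @rdname dosages
#' @export
setGeneric("dosages", function(x, ...) standardGeneric("dosages"))

#' @rdname dosages
#' @export
setGeneric("haplotypes", function(x, ...) standardGeneric("haplotypes"))

#' @rdname accessors
#' @export
setGeneric("ancestry", function(x, ...) standardGeneric("ancestry"))

#' @rdname accessors
#' @export
setGeneric("ldScores", function(x, ...) standardGeneric("ldScores"))

#' @rdname accessors
#' @export
setGeneric("qcPass", function(x, ...) standardGeneric("qcPass"))

#' @rdname accessors
#' @export
setGeneric("h2PerBin", function(x, ...) standardGeneric("h2PerBin"))

#' @rdname accessors
#' @export
setGeneric("h2Nim", function(x, ...) standardGeneric("h2Nim"))

#' @rdname accessors
#' @export
setGeneric("deltaH2", function(x, ...) standardGeneric("deltaH2"))

#' @rdname accessors
#' @export
setGeneric("binSizes", function(x, ...) standardGeneric("binSizes"))

#' @rdname accessors
#' @export
setGeneric("binLabels", function(x, ...) standardGeneric("binLabels"))

#' @rdname accessors
#' @export
setGeneric("binAssignment", function(x, ...) standardGeneric("binAssignment"))

#' @rdname accessors
#' @export
setGeneric("droppedBins", function(x, ...) standardGeneric("droppedBins"))
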