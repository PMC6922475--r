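#' @rdname timeGrid
#' @export
setGeneric("timeGrid", function(x) standardGeneric("timeGrid"))

#' @rdname timeGrid
#' @export
setGeneric("gridTimes", function(x) standardGeneric("gridTimes"))

#' @rdname timeGrid
#' @export
setGeneric("gridInterval", function(x) standardGeneric("gridInterval"))

#' @rdname timeGrid
#' @export
setGeneric("gridDropped", function(x) standardGeneric("gridDropped"))

#' @rdname fitTable
#' @export
setGeneric("fitTable", function(x, ...) standardGeneric("fitTable"))

#' @rdname dynamicGenes
#' @export
setGeneric("dynamicGenes", function(x, ...) standardGeneric("dynamicGenes"))

#' @rdname groundTruth
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
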