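#' @rdname LineageSet-class
#' @param x,object a \code{LineageSet}.
#' @export
setGeneric("lineageIds", function(x) standardGeneric("lineageIds"))

#' @rdname LineageSet-class
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @rdname LineageSet-class
#' @export
setGeneric("fragmentLabel", function(x) standardGeneric("fragmentLabel"))

#' @rdname AffinityTable-class
#' @param x an \code{AffinityTable}.
#' @export
setGeneric("affinityValues", function(x) standardGeneric("affinityValues"))

#' @rdname AffinityTable-class
#' @export
setGeneric("categorySizes", function(x) standardGeneric("categorySizes"))

#' @rdname HaplotypeNetwork-class
#' @param x a \code{HaplotypeNetwork}.
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname HaplotypeNetwork-class
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname ConstrainedOrdination-class
#' @param object a result object.
#' @export
setGeneric("ordinationSummary",
           function(object) standardGeneric("ordinationSummary"))
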