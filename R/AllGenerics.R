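#' @rdname HaplotypeMatrix-accessors
#' @export
setGeneric("nHaplotypes", function(x) standardGeneric("nHaplotypes"))

#' @rdname HaplotypeMatrix-accessors
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @rdname HaplotypeMatrix-accessors
#' @export
setGeneric("alleleMatrix", function(x) standardGeneric("alleleMatrix"))

#' @rdname HaplotypeMatrix-accessors
#' @export
setGeneric("populationLabels", function(x) standardGeneric("populationLabels"))

#' @rdname HaplotypeMatrix-accessors
#' @export
setGeneric("sitePositions", function(x) standardGeneric("sitePositions"))

#' @rdname HaplotypeMatrix-accessors
#' @export
setGeneric("annotationClass", function(x) standardGeneric("annotationClass"))

#' @rdname networkProperties
#' @export
setGeneric("nVertices", function(net) standardGeneric("nVertices"))

#' @rdname networkProperties
#' @export
setGeneric("averagePathLength", function(net) standardGeneric("averagePathLength"))

#' @rdname networkProperties
#' @export
setGeneric("nComponents", function(net) standardGeneric("nComponents"))

#' @rdname networkProperties
#' @export
setGeneric("averageDegree", function(net) standardGeneric("averageDegree"))

#' @rdname networkProperties
#' @export
setGeneric("verticesPerComponent",
           function(net) standardGeneric("verticesPerComponent"))

#' @rdname networkProperties
#' @export
setGeneric("networkProperties", function(net) standardGeneric("networkProperties"))
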