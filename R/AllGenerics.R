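#' @rdname TrnaAlignment-class
#' @param x a \code{TrnaAlignment}.
#' @export
setGeneric("nStrand", function(x) standardGeneric("nStrand"))

#' @rdname TrnaAlignment-class
#' @export
setGeneric("strandIds", function(x) standardGeneric("strandIds"))

#' @rdname TrnaAlignment-class
#' @export
setGeneric("strandClasses", function(x) standardGeneric("strandClasses"))

#' @rdname TrnaAlignment-class
#' @export
setGeneric("strandCodes", function(x) standardGeneric("strandCodes"))

#' @rdname TrnaAlignment-class
#' @export
setGeneric("alphabet", function(x) standardGeneric("alphabet"))

#' @rdname TrnaAlignment-class
#' @export
setGeneric("classTable", function(x) standardGeneric("classTable"))

#' @rdname ClassTable-class
#' @param x a \code{ClassTable}.
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname TrnaFeatureMatrix-class
#' @param x a \code{TrnaFeatureMatrix}.
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname TrnaFeatureMatrix-class
#' @export
setGeneric("featureInfo", function(x) standardGeneric("featureInfo"))
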