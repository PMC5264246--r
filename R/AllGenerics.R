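#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @rdname accessors
#' @export
setGeneric("nodeNames", function(x) standardGeneric("nodeNames"))

#' @rdname accessors
#' @export
setGeneric("tableValues", function(x) standardGeneric("tableValues"))

#' @rdname accessors
#' @export
setGeneric("basisMatrix", function(x) standardGeneric("basisMatrix"))

#' @rdname closure
#' @export
setGeneric("closure", function(x) standardGeneric("closure"))

#' @rdname addPseudocount
#' @export
setGeneric("addPseudocount", function(x, pseudocount = 1)
    standardGeneric("addPseudocount"))

#' @rdname perturbation
#' @export
setGeneric("perturbation", function(x, y) standardGeneric("perturbation"))

#' @rdname perturbation
#' @export
setGeneric("powering", function(x, t) standardGeneric("powering"))

#' @rdname regression-accessors
#' @export
setGeneric("coefTable", function(x) standardGeneric("coefTable"))

#' @rdname regression-accessors
#' @export
setGeneric("globalR2", function(x) standardGeneric("globalR2"))

#' @rdname regression-accessors
#' @export
setGeneric("fittedBalances", function(x) standardGeneric("fittedBalances"))

#' @rdname regression-accessors
#' @export
setGeneric("residualBalances", function(x) standardGeneric("residualBalances"))
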