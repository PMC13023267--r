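#' @include utils.R
NULL

#' @export
setGeneric("chromNames", function(x) standardGeneric("chromNames"))

#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @export
setGeneric("chromClasses", function(x) standardGeneric("chromClasses"))

#' @export
setGeneric("sampleNames", function(x) standardGeneric("sampleNames"))

#' @export
setGeneric("numVariants", function(x) standardGeneric("numVariants"))

#' @export
setGeneric("variantKeys", function(x) standardGeneric("variantKeys"))

#' @export
setGeneric("variantClass", function(x) standardGeneric("variantClass"))

#' @export
setGeneric("gtMatrix", function(x) standardGeneric("gtMatrix"))

#' @export
setGeneric("adAlt", function(x) standardGeneric("adAlt"))

#' @export
setGeneric("adRef", function(x) standardGeneric("adRef"))

#' @export
setGeneric("dpMatrix", function(x) standardGeneric("dpMatrix"))

#' @export
setGeneric("gqMatrix", function(x) standardGeneric("gqMatrix"))
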