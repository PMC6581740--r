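#' @import methods
#' @importFrom stats approx cor median p.adjust pbeta pt quantile rlnorm runif sd setNames
#' @importFrom utils head
NULL

#' @export
setGeneric("fragmentData", function(object, ...) standardGeneric("fragmentData"))

#' @export
setGeneric("sampleDesign", function(object, ...) standardGeneric("sampleDesign"))

#' @export
setGeneric("quantData", function(object, ...) standardGeneric("quantData"))

#' @export
setGeneric("scaleType", function(object) standardGeneric("scaleType"))

#' @export
setGeneric("quantLevel", function(object) standardGeneric("quantLevel"))
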