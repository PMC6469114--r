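#' @include AllClasses.R
NULL

#' @export
setGeneric("scaffolds", function(x, ...) standardGeneric("scaffolds"))

#' @export
setGeneric("depthTracks", function(x, ...) standardGeneric("depthTracks"))

#' @export
setGeneric("taxonHits", function(x, ...) standardGeneric("taxonHits"))

#' @export
setGeneric("truthTable", function(x, ...) standardGeneric("truthTable"))

#' @export
setGeneric("simConfig", function(x, ...) standardGeneric("simConfig"))

#' @export
setGeneric("altAssemblies", function(x, ...) standardGeneric("altAssemblies"))

#' @export
setGeneric("hgtCalls", function(x, ...) standardGeneric("hgtCalls"))

#' @export
setGeneric("classification", function(x, ...) standardGeneric("classification"))

#' @export
setGeneric("callReport", function(x, ...) standardGeneric("callReport"))

#' @export
setGeneric("multiStrain", function(x, ...) standardGeneric("multiStrain"))
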