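#' @rdname accessors
#' @export
setGeneric("lineIds", function(x) standardGeneric("lineIds"))

#' @rdname accessors
#' @export
setGeneric("sexCodes", function(x) standardGeneric("sexCodes"))

#' @rdname accessors
#' @export
setGeneric("phenoValues", function(x) standardGeneric("phenoValues"))

#' @rdname accessors
#' @export
setGeneric("studyId", function(x) standardGeneric("studyId"))

#' @rdname accessors
#' @export
setGeneric("studies", function(x) standardGeneric("studies"))

#' @rdname accessors
#' @export
setGeneric("descriptors", function(x) standardGeneric("descriptors"))

#' @rdname accessors
#' @export
setGeneric("phenoTables", function(x) standardGeneric("phenoTables"))

#' @rdname accessors
#' @export
setGeneric("variantInfo", function(x) standardGeneric("variantInfo"))

#' @rdname accessors
#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))

#' @rdname accessors
#' @export
setGeneric("covariateData", function(x) standardGeneric("covariateData"))
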