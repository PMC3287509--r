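#' @rdname accessors
#' @export
setGeneric("copyNumber", function(x) standardGeneric("copyNumber"))

#' @rdname accessors
#' @export
setGeneric("copyString", function(x) standardGeneric("copyString"))

#' @rdname accessors
#' @export
setGeneric("locusId", function(x) standardGeneric("locusId"))

#' @rdname accessors
#' @export
setGeneric("periodInstances", function(x) standardGeneric("periodInstances"))

#' @rdname accessors
#' @export
setGeneric("ampliconLength", function(x) standardGeneric("ampliconLength"))

#' @rdname accessors
#' @export
setGeneric("alleles", function(x) standardGeneric("alleles"))

#' @rdname accessors
#' @export
setGeneric("qcPassed", function(x) standardGeneric("qcPassed"))

#' @rdname accessors
#' @export
setGeneric("ankRepeats", function(x) standardGeneric("ankRepeats"))

#' @rdname accessors
#' @export
setGeneric("tmSegments", function(x) standardGeneric("tmSegments"))

#' @rdname accessors
#' @export
setGeneric("prematureStop", function(x) standardGeneric("prematureStop"))

#' @rdname accessors
#' @export
setGeneric("massKda", function(x) standardGeneric("massKda"))
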