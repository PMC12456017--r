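#' @rdname gcContent
#' @export
setGeneric("gcContent", function(x, ...) standardGeneric("gcContent"))

#' @rdname repliconAccessors
#' @export
setGeneric("repliconIds", function(x) standardGeneric("repliconIds"))

#' @rdname repliconAccessors
#' @export
setGeneric("repliconLengths", function(x) standardGeneric("repliconLengths"))

#' @rdname repliconAccessors
#' @export
setGeneric("assemblyId", function(x) standardGeneric("assemblyId"))

#' @rdname repliconAccessors
#' @export
setGeneric("repliconSource", function(x) standardGeneric("repliconSource"))

#' @rdname classificationAccessors
#' @export
setGeneric("roleCalls", function(x) standardGeneric("roleCalls"))

#' @rdname classificationAccessors
#' @export
setGeneric("clusters", function(x) standardGeneric("clusters"))

#' @rdname metrics
#' @export
setGeneric("accuracy", function(x, ...) standardGeneric("accuracy"))

#' @rdname metrics
#' @export
setGeneric("precision", function(x, ...) standardGeneric("precision"))

#' @rdname metrics
#' @export
setGeneric("tpr", function(x, ...) standardGeneric("tpr"))

#' @rdname metrics
#' @export
setGeneric("fpr", function(x, ...) standardGeneric("fpr"))
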