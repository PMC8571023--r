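#' @rdname CompoundLibrary-class
#' @param object,x a \code{CompoundLibrary}.
#' @export
setGeneric("compoundIds", function(object) standardGeneric("compoundIds"))

#' @rdname CompoundLibrary-class
#' @export
setGeneric("compoundNames", function(object) standardGeneric("compoundNames"))

#' @rdname CompoundLibrary-class
#' @export
setGeneric("compoundSmiles",
           function(object) standardGeneric("compoundSmiles"))

#' @rdname CompoundLibrary-class
#' @export
setGeneric("librarySource", function(object) standardGeneric("librarySource"))

#' @rdname FingerprintSet-class
#' @param object a \code{FingerprintSet}.
#' @export
setGeneric("fingerprintScheme",
           function(object) standardGeneric("fingerprintScheme"))

#' @rdname FingerprintSet-class
#' @export
setGeneric("fingerprintValues",
           function(object) standardGeneric("fingerprintValues"))

#' @rdname SimilarityMatrix-class
#' @param object a \code{SimilarityMatrix} (or other container with values).
#' @export
setGeneric("similarityValues",
           function(object) standardGeneric("similarityValues"))

#' @rdname ClusterTree-class
#' @param object a \code{ClusterTree}.
#' @export
setGeneric("clusterAssignments",
           function(object) standardGeneric("clusterAssignments"))

#' @rdname LeadReport-class
#' @param object a \code{LeadReport}.
#' @export
setGeneric("leadIds", function(object) standardGeneric("leadIds"))

#' @rdname LeadReport-class
#' @export
setGeneric("reportTable", function(object) standardGeneric("reportTable"))
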