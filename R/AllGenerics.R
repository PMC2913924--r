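#' @rdname regionLength
#' @export
setGeneric("regionLength", function(x) standardGeneric("regionLength"))

#' @rdname regionSequence
#' @export
setGeneric("regionSequence", function(x) standardGeneric("regionSequence"))

#' @rdname annotation-accessors
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))

#' @rdname annotation-accessors
#' @export
setGeneric("transcripts", function(x) standardGeneric("transcripts"))

#' @rdname annotation-accessors
#' @export
setGeneric("proteinDomains", function(x) standardGeneric("proteinDomains"))

#' @rdname annotation-accessors
#' @export
setGeneric("repeatFeatures", function(x) standardGeneric("repeatFeatures"))

#' @rdname annotation-accessors
#' @export
setGeneric("knownVariants", function(x) standardGeneric("knownVariants"))

#' @rdname variant-accessors
#' @export
setGeneric("variantType", function(x) standardGeneric("variantType"))

#' @rdname variant-accessors
#' @export
setGeneric("plusAllele", function(x) standardGeneric("plusAllele"))

#' @rdname tree-accessors
#' @export
setGeneric("isIntergenic", function(x) standardGeneric("isIntergenic"))

#' @rdname tree-accessors
#' @export
setGeneric("knownIds", function(x) standardGeneric("knownIds"))

#' @rdname tree-accessors
#' @export
setGeneric("repeatNames", function(x) standardGeneric("repeatNames"))

#' @rdname tree-accessors
#' @export
setGeneric("geneBranches", function(x) standardGeneric("geneBranches"))

#' @rdname tree-accessors
#' @export
setGeneric("labelSet", function(x) standardGeneric("labelSet"))
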