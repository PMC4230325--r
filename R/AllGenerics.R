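#' Accessors for CTCExperiment and friends
#'
#' \code{exprUnit} returns the declared unit; \code{exprValues} the dense
#' gene-by-cell matrix; \code{geneIds}/\code{cellIds} the identifiers;
#' \code{cellData} the per-cell annotation table. \code{geneSets} returns
#' the named list held by a \linkS4class{GeneSetList};
#' \code{clusterLabels} the named label vector of a
#' \linkS4class{ClusterAssignment}.
#'
#' @param x the object.
#' @param value replacement value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("exprUnit", function(x) standardGeneric("exprUnit"))
#' @rdname accessors
#' @export
setGeneric("exprUnit<-", function(x, value) standardGeneric("exprUnit<-"))
#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))
#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))
#' @rdname accessors
#' @export
setGeneric("cellData", function(x) standardGeneric("cellData"))
#' @rdname accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))
#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname accessors
#' @export
setMethod("exprUnit", "CTCExperiment", function(x) x@unit)

#' @rdname accessors
#' @export
setReplaceMethod("exprUnit", "CTCExperiment", function(x, value) {
  x@unit <- value
  validObject(x)
  x
})

#' @rdname accessors
#' @export
setMethod("exprValues", "CTCExperiment", function(x)
  SummarizedExperiment::assay(x, "expr"))

#' @rdname accessors
#' @export
setMethod("geneIds", "CTCExperiment", function(x) rownames(x))

#' @rdname accessors
#' @export
setMethod("cellIds", "CTCExperiment", function(x) colnames(x))

#' @rdname accessors
#' @export
setMethod("cellData", "CTCExperiment", function(x)
  SummarizedExperiment::colData(x))

#' @rdname accessors
#' @export
setMethod("geneSets", "GeneSetList", function(x) x@sets)

#' @rdname accessors
#' @export
setMethod("clusterLabels", "ClusterAssignment", function(x) x@labels)

#' @rdname accessors
#' @param i set name or index.
#' @export
setMethod("[[", "GeneSetList", function(x, i) x@sets[[i]])

#' @rdname accessors
#' @export
setMethod("names", "GeneSetList", function(x) names(x@sets))

#' @rdname accessors
#' @export
setMethod("length", "GeneSetList", function(x) length(x@sets))
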