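#' Accessors for GlycoTFNet classes
#'
#' Small accessor generics giving read access to the slots of the package's
#' S4 containers without touching \code{@} directly.
#'
#' @param x an object of one of the package classes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname accessors
#' @export
setGeneric("geneSymbols", function(x) standardGeneric("geneSymbols"))

#' @rdname accessors
#' @export
setGeneric("pathwayNames", function(x) standardGeneric("pathwayNames"))

#' @rdname accessors
#' @export
setGeneric("classifiedGenes", function(x) standardGeneric("classifiedGenes"))

#' @rdname accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname accessors
#' @export
setGeneric("tfNodes", function(x) standardGeneric("tfNodes"))

#' @rdname accessors
#' @export
setGeneric("geneNodes", function(x) standardGeneric("geneNodes"))

#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname accessors
#' @export
setGeneric("communities", function(x) standardGeneric("communities"))

#' @rdname accessors
#' @export
setGeneric("communityModularity",
           function(x) standardGeneric("communityModularity"))

#' @rdname accessors
#' @export
setGeneric("plantedPairs", function(x) standardGeneric("plantedPairs"))

#' @rdname accessors
#' @export
setGeneric("plantedBlocks", function(x) standardGeneric("plantedBlocks"))

#' @rdname accessors
#' @export
setMethod("records", "TFGeneTable", function(x) x@records)

#' @rdname accessors
#' @export
setMethod("records", "SyntheticTruth", function(x) x@table@records)

#' @rdname accessors
#' @export
setMethod("geneSymbols", "GeneSet", function(x) x@members)

#' @rdname accessors
#' @export
setMethod("pathwayNames", "PathwayClassification",
          function(x) sort(unique(x@membership$pathway)))

#' @rdname accessors
#' @export
setMethod("classifiedGenes", "PathwayClassification",
          function(x) sort(unique(x@membership$gene)))

#' @rdname accessors
#' @export
setMethod("records", "PathwayClassification", function(x) x@membership)

#' @rdname accessors
#' @export
setMethod("geneSets", "AnnotationCollection", function(x) x@sets)

#' @rdname accessors
#' @export
setMethod("tfNodes", "BipartiteNetwork",
          function(x) sort(unique(x@edges$tf)))

#' @rdname accessors
#' @export
setMethod("geneNodes", "BipartiteNetwork",
          function(x) sort(unique(x@edges$gene)))

#' @rdname accessors
#' @export
setMethod("networkEdges", "BipartiteNetwork", function(x) x@edges)

#' @rdname accessors
#' @export
setMethod("communities", "TFCommunitySet", function(x) x@membership)

#' @rdname accessors
#' @export
setMethod("communityModularity", "TFCommunitySet", function(x) x@modularity)

#' @rdname accessors
#' @export
setMethod("plantedPairs", "SyntheticTruth", function(x) x@pairs)

#' @rdname accessors
#' @export
setMethod("plantedBlocks", "SyntheticTruth", function(x) x@blocks)
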