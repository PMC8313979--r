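#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

.validTFGeneRecords <- function(df) {
    required <- c("tf", "gene", "cancer", "rp", "rho")
    missing <- setdiff(required, colnames(df))
    if (length(missing) > 0L)
        return(sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
    if (nrow(df) > 0L) {
        for (col in c("tf", "gene", "cancer")) {
            bad <- which(is.na(df[[col]]) | !nzchar(trimws(df[[col]])))
            if (length(bad) > 0L)
                return(sprintf("empty '%s' symbol at row %d", col, bad[1L]))
        }
        bad <- which(is.na(df$rp) | df$rp < 0 | df$rp > 1)
        if (length(bad) > 0L)
            return(sprintf("rp out of [0, 1] at row %d", bad[1L]))
        bad <- which(is.na(df$rho) | df$rho < -1 | df$rho > 1)
        if (length(bad) > 0L)
            return(sprintf("rho out of [-1, 1] at row %d", bad[1L]))
        key <- paste(df$tf, df$gene, df$cancer, sep = "\r")
        if (anyDuplicated(key))
            return(sprintf("duplicate (tf, gene, cancer) record at row %d",
                           which(duplicated(key))[1L]))
    }
    TRUE
}

#' TFGeneTable: a table of TF-to-glycogene regulatory edges
#'
#' One row per (TF, target gene, cancer type) regulatory relationship as
#' exported from ChIP-Seq/RNA-Seq integration resources such as Cistrome
#' Cancer. Each edge carries a regulatory potential \code{rp} (0 to 1,
#' ChIP-Seq binding evidence near the TSS), a Spearman expression
#' correlation \code{rho} (-1 to 1) and the derived binding potential
#' \code{bp = rp * rho}.
#'
#' @slot records data.frame with columns \code{tf}, \code{gene},
#'   \code{cancer}, \code{rp}, \code{rho}, \code{bp}.
#' @exportClass TFGeneTable
setClass("TFGeneTable", representation(records = "data.frame"))

setValidity("TFGeneTable", function(object) {
    df <- object@records
    msg <- .validTFGeneRecords(df)
    if (!isTRUE(msg)) return(msg)
    if (!"bp" %in% colnames(df)) return("missing 'bp' column")
    if (nrow(df) > 0L && any(abs(df$bp - df$rp * df$rho) > 1e-12))
        return("bp must equal rp * rho")
    TRUE
})

#' GeneSet: a named set of gene symbols
#'
#' @slot name single set name.
#' @slot members unique, non-empty gene symbols.
#' @exportClass GeneSet
setClass("GeneSet",
         representation(name = "character", members = "character"))

setValidity("GeneSet", function(object) {
    if (length(object@name) != 1L || !nzchar(object@name))
        return("name must be a single non-empty string")
    if (length(object@members) == 0L)
        return("members must be non-empty")
    if (anyDuplicated(object@members))
        return("members must be unique")
    if (any(!nzchar(object@members)))
        return("members must be non-empty symbols")
    TRUE
})

#' PathwayClassification: many-to-many gene to glyco-pathway assignment
#'
#' Maps glycogenes to curated glycosylation pathways (e.g., "Sialylation",
#' "Dolichol pathway"). A gene may belong to several pathways, as for the
#' sialyltransferases shared between the ganglioside and sialylation groups.
#'
#' @slot membership data.frame with columns \code{gene} and \code{pathway},
#'   one row per membership, deduplicated.
#' @exportClass PathwayClassification
setClass("PathwayClassification",
         representation(membership = "data.frame"))

setValidity("PathwayClassification", function(object) {
    df <- object@membership
    if (!all(c("gene", "pathway") %in% colnames(df)))
        return("membership needs 'gene' and 'pathway' columns")
    if (nrow(df) == 0L) return("classification is empty")
    if (any(!nzchar(trimws(df$gene))) || any(is.na(df$gene)))
        return("empty gene symbol in classification")
    if (any(!nzchar(trimws(df$pathway))) || any(is.na(df$pathway)))
        return("empty pathway name in classification")
    if (anyDuplicated(paste(df$gene, df$pathway, sep = "\r")))
        return("duplicate (gene, pathway) membership")
    TRUE
})

#' AnnotationCollection: named gene sets (GMT-style)
#'
#' A local stand-in for signaling pathway collections such as Reactome,
#' held as a named list of member-symbol vectors.
#'
#' @slot sets named list of character vectors of gene symbols.
#' @slot source free-text provenance of the collection.
#' @exportClass AnnotationCollection
setClass("AnnotationCollection",
         representation(sets = "list", source = "character"))

setValidity("AnnotationCollection", function(object) {
    if (length(object@sets) == 0L) return("collection is empty")
    nm <- names(object@sets)
    if (is.null(nm) || any(!nzchar(nm))) return("all sets must be named")
    if (anyDuplicated(nm)) return("duplicate set name")
    if (any(vapply(object@sets, length, 1L) == 0L))
        return("empty gene set not allowed")
    TRUE
})

#' BipartiteNetwork: a TF-glycogene network for one cancer type
#'
#' TF and glycogene nodes form the two disjoint classes; edges are the
#' retained regulatory relationships with their rp, rho and bp attributes.
#'
#' @slot cancer single cancer-type code (e.g., "BRCA_1").
#' @slot edges data.frame with columns \code{tf}, \code{gene}, \code{rp},
#'   \code{rho}, \code{bp}.
#' @exportClass BipartiteNetwork
setClass("BipartiteNetwork",
         representation(cancer = "character", edges = "data.frame"))

setValidity("BipartiteNetwork", function(object) {
    if (length(object@cancer) != 1L)
        return("cancer must be a single code")
    df <- object@edges
    if (!all(c("tf", "gene", "rp", "rho", "bp") %in% colnames(df)))
        return("edges need tf, gene, rp, rho, bp columns")
    if (nrow(df) > 0L) {
        if (length(intersect(unique(df$tf), unique(df$gene))) > 0L)
            return("a symbol appears both as TF and as glycogene node")
        if (anyDuplicated(paste(df$tf, df$gene, sep = "\r")))
            return("duplicate (tf, gene) edge")
    }
    TRUE
})

#' TFCommunitySet: communities of a TF-glycogene network
#'
#' The partition of the TF nodes found by greedy modularity maximization on
#' the shared-target TF projection, together with the glycogenes assigned to
#' each community. Community ids are 1-based in order of decreasing TF
#' membership size.
#'
#' @slot cancer cancer-type code.
#' @slot membership data.frame with columns \code{node}, \code{type}
#'   ("TF" or "glycogene") and \code{community} (integer id).
#' @slot modularity modularity Q of the TF partition on the projected graph.
#' @exportClass TFCommunitySet
setClass("TFCommunitySet",
         representation(cancer = "character", membership = "data.frame",
                        modularity = "numeric"))

setValidity("TFCommunitySet", function(object) {
    df <- object@membership
    if (!all(c("node", "type", "community") %in% colnames(df)))
        return("membership needs node, type, community columns")
    if (nrow(df) > 0L) {
        if (!all(df$type %in% c("TF", "glycogene")))
            return("type must be 'TF' or 'glycogene'")
        if (anyDuplicated(df$node[df$type == "TF"]))
            return("a TF is assigned to more than one community")
        if (anyDuplicated(df$node[df$type == "glycogene"]))
            return("a glycogene is assigned to more than one community")
    }
    TRUE
})

#' SyntheticTruth: a generated dataset plus its ground truth
#'
#' @slot table generated [TFGeneTable-class].
#' @slot classification generated [PathwayClassification-class].
#' @slot collection generated signaling [AnnotationCollection-class].
#' @slot pairs data.frame of planted (cancer, tf, pathway, factor) rows.
#' @slot blocks named integer vector: planted block id per block TF.
#' @slot config the generating configuration list.
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
         representation(table = "TFGeneTable",
                        classification = "PathwayClassification",
                        collection = "AnnotationCollection",
                        pairs = "data.frame",
                        blocks = "integer",
                        config = "list"))

setMethod("show", "TFGeneTable", function(object) {
    df <- object@records
    cat(sprintf("TFGeneTable: %d edges, %d TFs, %d genes, %d cancer type(s)\n",
                nrow(df), length(unique(df$tf)), length(unique(df$gene)),
                length(unique(df$cancer))))
})

setMethod("show", "GeneSet", function(object) {
    cat(sprintf("GeneSet '%s': %d symbols\n", object@name,
                length(object@members)))
})

setMethod("show", "PathwayClassification", function(object) {
    df <- object@membership
    cat(sprintf("PathwayClassification: %d genes in %d pathways (%d memberships)\n",
                length(unique(df$gene)), length(unique(df$pathway)), nrow(df)))
})

setMethod("show", "AnnotationCollection", function(object) {
    cat(sprintf("AnnotationCollection (%s): %d sets, median size %d\n",
                object@source, length(object@sets),
                as.integer(stats::median(vapply(object@sets, length, 1L)))))
})

setMethod("show", "BipartiteNetwork", function(object) {
    df <- object@edges
    cat(sprintf("BipartiteNetwork [%s]: %d TFs, %d glycogenes, %d edges\n",
                object@cancer, length(unique(df$tf)),
                length(unique(df$gene)), nrow(df)))
})

setMethod("show", "TFCommunitySet", function(object) {
    df <- object@membership
    k <- length(unique(df$community))
    cat(sprintf("TFCommunitySet [%s]: %d communities, Q = %.4f\n",
                object@cancer, k, object@modularity))
})

setMethod("show", "SyntheticTruth", function(object) {
    cat("SyntheticTruth\n  ")
    show(object@table)
    cat(sprintf("  planted pairs: %d; planted block TFs: %d\n",
                nrow(object@pairs), length(object@blocks)))
})
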