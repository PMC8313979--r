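#' Gene-set overrepresentation of a TF query
#'
#' One-sided hypergeometric overrepresentation of a TF query set against a
#' signaling gene-set collection, mirroring a Reactome-style analysis but
#' run on local GMT collections. Each set is tested with
#' [hypergeometricTail()] on \code{k = |query %in% set|},
#' \code{K = |set %in% universe|}, \code{n = |query|}, \code{N = |universe|};
#' BH adjustment runs across the tested sets. Results are filtered to
#' \code{fdr < fdrMax} and \code{setSize < maxSetSize}, both strict.
#'
#' @param query character vector of TF symbols (must lie in the universe).
#' @param collection an [AnnotationCollection-class].
#' @param universe character vector of symbols forming the testing
#'   universe (e.g., all TFs of the cancer's filtered table).
#' @param fdrMax strict FDR cutoff applied to the output (default 0.1).
#' @param maxSetSize strict set-size cutoff (default 30; sets with 30 or
#'   more members are dropped).
#' @param filter set \code{FALSE} to return all tested sets unfiltered.
#' @return a [S4Vectors::DataFrame] with columns \code{setName},
#'   \code{setSize}, \code{hits} (comma-separated TFs), \code{k},
#'   \code{p}, \code{fdr}, ordered by p.
#' @export
overrepresent <- function(query, collection, universe, fdrMax = 0.1,
                          maxSetSize = 30, filter = TRUE) {
    stopifnot(is(collection, "AnnotationCollection"))
    universe <- unique(as.character(universe))
    if (length(universe) == 0L) stop("domain error: empty universe")
    query <- unique(as.character(query))
    if (!all(query %in% universe))
        stop("domain error: query symbols outside the universe: ",
             paste(setdiff(query, universe), collapse = ", "))
    sets <- geneSets(collection)
    res <- do.call(rbind, lapply(names(sets), function(nm) {
        members <- sets[[nm]]
        inUniverse <- intersect(members, universe)
        hits <- intersect(query, inUniverse)
        data.frame(setName = nm,
                   setSize = length(members),
                   hits = paste(sort(hits), collapse = ","),
                   k = length(hits),
                   K = length(inUniverse),
                   stringsAsFactors = FALSE)
    }))
    res$p <- hypergeometricTail(res$k, res$K, length(query),
                                length(universe))
    res$fdr <- benjaminiHochberg(res$p)
    if (filter)
        res <- res[res$fdr < fdrMax & res$setSize < maxSetSize, ,
                   drop = FALSE]
    res <- res[order(res$p, res$setName), , drop = FALSE]
    rownames(res) <- NULL
    DataFrame(res[, c("setName", "setSize", "hits", "k", "p", "fdr")])
}

#' Alluvial flow table: signaling sets -> TFs -> glyco-pathways
#'
#' Links the kept signaling overrepresentation results to the significant
#' TF-glycopathway enrichments of one cancer type: one flow row per
#' (signaling set containing the TF, TF, enriched glyco-pathway), weighted
#' by the TF's retained edge count into that pathway. TFs enriched to a
#' glyco-pathway but absent from every kept signaling set are emitted with
#' \code{signalingSet = "(unassigned)"}, so no glyco-enriched TF is lost
#' from the flow table.
#'
#' @param glycoEnrichments significant rows of [enrichTFPathways()] output
#'   for one cancer (data.frame or DataFrame with \code{tf},
#'   \code{pathway}, \code{cancer}).
#' @param signalingResults kept rows of [overrepresent()] output
#'   (\code{setName}, \code{hits}).
#' @param edges the cancer's retained edges.
#' @param classification a [PathwayClassification-class] (defines which
#'   edges count toward a pathway for the flow weight).
#' @return a [S4Vectors::DataFrame] with columns \code{signalingSet},
#'   \code{tf}, \code{glycoPathway}, \code{weight}, \code{cancer}.
#' @export
buildAlluvialFlows <- function(glycoEnrichments, signalingResults, edges,
                               classification) {
    gl <- as.data.frame(glycoEnrichments)
    sig <- as.data.frame(signalingResults)
    df <- .edgeFrame(edges)
    if (nrow(gl) == 0L)
        return(DataFrame(signalingSet = character(), tf = character(),
                         glycoPathway = character(), weight = integer(),
                         cancer = character()))
    if (length(unique(gl$cancer)) > 1L)
        stop("domain error: flows are built per cancer type")
    pathways <- .pathwayList(classification)
    tfSets <- if (nrow(sig) > 0L)
        lapply(strsplit(sig$hits, ",", fixed = TRUE), trimws)
    else list()
    out <- do.call(rbind, lapply(seq_len(nrow(gl)), function(i) {
        tf <- gl$tf[i]; pw <- gl$pathway[i]
        weight <- sum(df$tf == tf & df$gene %in% pathways[[pw]])
        if (weight < 1L) return(NULL)
        inSets <- if (length(tfSets) > 0L)
            sig$setName[vapply(tfSets, function(s) tf %in% s, TRUE)]
        else character()
        if (length(inSets) == 0L) inSets <- "(unassigned)"
        data.frame(signalingSet = inSets, tf = tf, glycoPathway = pw,
                   weight = as.integer(weight), cancer = gl$cancer[i],
                   stringsAsFactors = FALSE)
    }))
    if (is.null(out))
        return(DataFrame(signalingSet = character(), tf = character(),
                         glycoPathway = character(), weight = integer(),
                         cancer = character()))
    out <- out[order(out$signalingSet, out$tf, out$glycoPathway), ,
               drop = FALSE]
    rownames(out) <- NULL
    DataFrame(out)
}
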