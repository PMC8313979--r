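#' Binding potential score
#'
#' The binding potential (BP) of a TF-gene edge is the product of its
#' regulatory potential and its Spearman expression correlation,
#' \code{bp = rp * rho}. It summarizes binding evidence and expression
#' coupling in one score and is used as an edge weight for network export
#' and layout.
#'
#' @param rp regulatory potential in \[0, 1\] (vectorized).
#' @param rho Spearman correlation in \[-1, 1\] (vectorized).
#' @return numeric vector of products.
#' @examples
#' bindingPotential(0.94, 0.56)
#' @export
bindingPotential <- function(rp, rho) {
    if (any(rp < 0 | rp > 1, na.rm = TRUE))
        stop("rp out of [0, 1]")
    if (any(rho < -1 | rho > 1, na.rm = TRUE))
        stop("rho out of [-1, 1]")
    rp * rho
}

#' Filter TF-gene edges to the glycogene universe and score thresholds
#'
#' Retains exactly the records whose target gene lies in the glycogene
#' universe and whose regulatory potential and correlation meet the
#' inclusive thresholds \code{rp >= rpMin} and \code{rho >= rhoMin}
#' (defaults RP >= 0.5, rho >= 0.4, selecting positive regulatory
#' relationships). Row order is preserved and the operation is idempotent.
#'
#' @param x a [TFGeneTable-class].
#' @param universe a [GeneSet-class] of glycogene symbols, or a character
#'   vector; \code{NULL} disables the universe restriction.
#' @param rpMin regulatory-potential threshold in \[0, 1\].
#' @param rhoMin correlation threshold in \[-1, 1\].
#' @return a filtered [TFGeneTable-class] (possibly with zero rows).
#' @export
filterRecords <- function(x, universe = NULL, rpMin = 0.5, rhoMin = 0.4) {
    stopifnot(is(x, "TFGeneTable"))
    if (rpMin < 0 || rpMin > 1) stop("rpMin out of [0, 1]")
    if (rhoMin < -1 || rhoMin > 1) stop("rhoMin out of [-1, 1]")
    df <- x@records
    keep <- df$rp >= rpMin & df$rho >= rhoMin
    if (!is.null(universe)) {
        members <- if (is(universe, "GeneSet")) universe@members
                   else as.character(universe)
        keep <- keep & df$gene %in% members
    }
    out <- df[keep, , drop = FALSE]
    rownames(out) <- NULL
    new("TFGeneTable", records = out)
}

#' Summarize a TF-gene table
#'
#' Global and per-cancer counts of edges, unique TFs and unique target
#' genes, plus the per-TF out-degree distribution within each cancer type
#' (the number of glycogenes each TF regulates in that cancer).
#'
#' @param x a [TFGeneTable-class].
#' @return a list with elements \code{global} (one-row data.frame),
#'   \code{perCancer} (one row per cancer code) and \code{outDegree}
#'   (one row per (cancer, tf) with its target count).
#' @export
summarizeTable <- function(x) {
    stopifnot(is(x, "TFGeneTable"))
    df <- x@records
    global <- data.frame(edges = nrow(df),
                         tfs = length(unique(df$tf)),
                         genes = length(unique(df$gene)),
                         cancers = length(unique(df$cancer)))
    if (nrow(df) == 0L) {
        perCancer <- data.frame(cancer = character(), edges = integer(),
                                tfs = integer(), genes = integer())
        outDegree <- data.frame(cancer = character(), tf = character(),
                                degree = integer())
        return(list(global = global, perCancer = perCancer,
                    outDegree = outDegree))
    }
    sp <- split(df, df$cancer)
    perCancer <- do.call(rbind, lapply(names(sp), function(cc) {
        d <- sp[[cc]]
        data.frame(cancer = cc, edges = nrow(d),
                   tfs = length(unique(d$tf)),
                   genes = length(unique(d$gene)))
    }))
    outDegree <- do.call(rbind, lapply(names(sp), function(cc) {
        tab <- table(sp[[cc]]$tf)
        data.frame(cancer = cc, tf = names(tab),
                   degree = as.integer(tab))
    }))
    rownames(perCancer) <- rownames(outDegree) <- NULL
    list(global = global, perCancer = perCancer, outDegree = outDegree)
}
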