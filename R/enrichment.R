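#' Upper-tail hypergeometric probability (one-sided Fisher's exact test)
#'
#' Probability of observing at least \code{k} successes when drawing
#' \code{n} items without replacement from a population of size \code{N}
#' containing \code{K} successes:
#' \deqn{p = \sum_{j=k}^{\min(K,n)} \binom{K}{j}\binom{N-K}{n-j} / \binom{N}{n}.}
#' For a 2x2 table with fixed margins this equals the one-sided
#' ("greater") Fisher exact p-value used for overrepresentation testing.
#' All arguments are vectorized.
#'
#' @param k observed successes in the draw.
#' @param K successes in the population.
#' @param n draw size.
#' @param N population size.
#' @return p-values in (0, 1\]; \code{k = 0} gives exactly 1.
#' @examples
#' hypergeometricTail(3, 5, 4, 10)   # 55/210
#' hypergeometricTail(2, 2, 2, 10)   # 1/45
#' @export
hypergeometricTail <- function(k, K, n, N) {
    v <- cbind(k = k, K = K, n = n, N = N)
    if (any(v != floor(v)) || any(v < 0))
        stop("domain error: counts must be non-negative integers")
    if (any(v[, "K"] > v[, "N"]) || any(v[, "n"] > v[, "N"]))
        stop("domain error: K and n must not exceed N")
    if (any(v[, "k"] > pmin(v[, "K"], v[, "n"])))
        stop("domain error: k must not exceed min(K, n)")
    unname(stats::phyper(v[, "k"] - 1L, v[, "K"], v[, "N"] - v[, "K"],
                         v[, "n"], lower.tail = FALSE))
}

.edgeFrame <- function(edges) {
    if (is(edges, "TFGeneTable")) return(edges@records)
    if (is(edges, "BipartiteNetwork")) {
        df <- edges@edges
        df$cancer <- edges@cancer
        return(df)
    }
    stopifnot(is.data.frame(edges))
    edges
}

.pathwayList <- function(classification) {
    split(classification@membership$gene, classification@membership$pathway)
}

#' Build the 2x2 contingency table for one TF and one pathway
#'
#' Within one cancer type's retained edges, counts: \code{a}, the focal
#' TF's edges whose target is in the pathway; \code{b}, its remaining
#' edges; \code{c}, the other TFs' edges in the pathway; \code{d}, the
#' other TFs' remaining edges. An edge counts toward the pathway iff its
#' gene's classification includes that pathway; edges to unclassified
#' genes count as "not in pathway".
#'
#' @param tf focal TF symbol.
#' @param pathway pathway name.
#' @param edges retained edges of a single cancer type: a
#'   [TFGeneTable-class], [BipartiteNetwork-class] or data.frame.
#' @param classification a [PathwayClassification-class].
#' @return named integer vector \code{c(a, b, c, d)}.
#' @export
buildContingency <- function(tf, pathway, edges, classification) {
    df <- .edgeFrame(edges)
    if (length(unique(df$cancer)) > 1L)
        stop("domain error: edges span more than one cancer type")
    if (!tf %in% df$tf)
        stop("domain error: TF '", tf, "' has no retained edge here")
    genes <- .pathwayList(classification)[[pathway]]
    if (is.null(genes)) genes <- character()
    focal <- df$tf == tf
    inPath <- df$gene %in% genes
    a <- sum(focal & inPath)
    b <- sum(focal & !inPath)
    cc <- sum(!focal & inPath)
    d <- sum(!focal & !inPath)
    c(a = a, b = b, c = cc, d = d)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH false-discovery-rate adjustment: with p-values sorted
#' ascending, \code{adj_i = min_{j >= i} (m * p_j / j)}, capped at 1 and
#' returned in input order (delegates to [stats::p.adjust()]).
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in input order.
#' @examples
#' benjaminiHochberg(c(0.01, 0.02, 0.03, 0.04))
#' @export
benjaminiHochberg <- function(p) {
    if (any(is.na(p)) || any(p < 0 | p > 1))
        stop("domain error: p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Per-cancer TF-to-glycopathway enrichment
#'
#' For every cancer type and every TF with at least one retained edge in
#' that cancer, tests each glycosylation pathway for disproportionate
#' regulation with a one-sided Fisher's exact test
#' ([hypergeometricTail()] on the 2x2 counts of [buildContingency()]),
#' using all retained TF-gene relationships of the cancer as background.
#' Raw p-values are BH-adjusted either in one global pool across all
#' cancer types (default) or within each cancer.
#'
#' @param x retained edges: a [TFGeneTable-class] (typically the output of
#'   [filterRecords()]).
#' @param classification a [PathwayClassification-class].
#' @param alphaRaw raw-p screening level for the \code{significant} flag
#'   (default 0.05, \code{p <= alphaRaw}).
#' @param bhScope \code{"global"} (one BH pool across cancers) or
#'   \code{"per_cancer"}.
#' @param backgroundClassifiedOnly restrict the background margin to edges
#'   whose target gene is classified (default \code{FALSE}: all retained
#'   edges form the background).
#' @return a [S4Vectors::DataFrame] with columns \code{cancer}, \code{tf},
#'   \code{pathway}, \code{a}, \code{b}, \code{c}, \code{d}, \code{p},
#'   \code{pAdj}, \code{significant}.
#' @export
enrichTFPathways <- function(x, classification, alphaRaw = 0.05,
                             bhScope = c("global", "per_cancer"),
                             backgroundClassifiedOnly = FALSE) {
    bhScope <- match.arg(bhScope)
    stopifnot(is(classification, "PathwayClassification"))
    df <- .edgeFrame(x)
    pathways <- .pathwayList(classification)
    if (backgroundClassifiedOnly)
        df <- df[df$gene %in% unique(classification@membership$gene), ,
                 drop = FALSE]
    out <- lapply(split(df, df$cancer), function(d) {
        tfs <- sort(unique(d$tf))
        tfFac <- factor(d$tf, levels = tfs)
        nEdges <- as.integer(table(tfFac))
        N <- nrow(d)
        res <- lapply(names(pathways), function(pw) {
            inP <- d$gene %in% pathways[[pw]]
            K <- sum(inP)
            a <- as.integer(table(tfFac[inP]))
            data.frame(cancer = d$cancer[1L], tf = tfs, pathway = pw,
                       a = a, b = nEdges - a, c = K - a,
                       d = N - nEdges - K + a,
                       p = stats::phyper(a - 1L, K, N - K, nEdges,
                                         lower.tail = FALSE),
                       stringsAsFactors = FALSE)
        })
        do.call(rbind, res)
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    if (nrow(out) == 0L) {
        out$pAdj <- numeric()
        out$significant <- logical()
        return(DataFrame(out))
    }
    out <- out[order(out$cancer, out$tf, out$pathway), , drop = FALSE]
    rownames(out) <- NULL
    if (bhScope == "global") {
        out$pAdj <- benjaminiHochberg(out$p)
    } else {
        out$pAdj <- NA_real_
        for (cc in unique(out$cancer)) {
            i <- out$cancer == cc
            out$pAdj[i] <- benjaminiHochberg(out$p[i])
        }
    }
    out$significant <- out$p <= alphaRaw
    DataFrame(out)
}

#' Degree of regulation per cancer-glycopathway pair
#'
#' For each (cancer, pathway) pair, counts the TFs whose adjusted p-value
#' falls below \code{alphaAdj} and sums their \code{-log10(pAdj)} into a
#' single "degree of regulation". Pairs with no significant TF report
#' \code{nTFs = 0} and \code{degree = 0}.
#'
#' @param results output of [enrichTFPathways()] (must carry \code{pAdj}).
#' @param alphaAdj adjusted-p significance level (default 0.05, strict
#'   \code{pAdj < alphaAdj}).
#' @return a [S4Vectors::DataFrame] with columns \code{cancer},
#'   \code{pathway}, \code{nTFs}, \code{degree}.
#' @export
degreeOfRegulation <- function(results, alphaAdj = 0.05) {
    res <- as.data.frame(results)
    stopifnot(all(c("cancer", "pathway", "pAdj") %in% colnames(res)))
    key <- interaction(res$cancer, res$pathway, drop = TRUE, sep = "\r")
    sig <- res$pAdj < alphaAdj
    nTFs <- tapply(sig, key, sum)
    degree <- tapply(ifelse(sig, -log10(res$pAdj), 0), key, sum)
    parts <- strsplit(names(nTFs), "\r", fixed = TRUE)
    out <- data.frame(cancer = vapply(parts, `[`, "", 1L),
                      pathway = vapply(parts, `[`, "", 2L),
                      nTFs = as.integer(nTFs),
                      degree = as.numeric(degree),
                      stringsAsFactors = FALSE)
    out <- out[order(out$cancer, out$pathway), , drop = FALSE]
    rownames(out) <- NULL
    DataFrame(out)
}
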