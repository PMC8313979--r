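#' Build the bipartite TF-glycogene network of one cancer type
#'
#' Nodes are the TFs and glycogenes of the retained edges; each edge keeps
#' its rp, rho and bp attributes for export and layout weighting.
#'
#' @param x retained edges of a single cancer: a [TFGeneTable-class] or
#'   data.frame with columns \code{tf}, \code{gene}, \code{cancer},
#'   \code{rp}, \code{rho} (and optionally \code{bp}).
#' @param cancer optional cancer code for an empty network.
#' @return a [BipartiteNetwork-class].
#' @export
buildBipartite <- function(x, cancer = NULL) {
    df <- .edgeFrame(x)
    if (nrow(df) == 0L) {
        return(new("BipartiteNetwork",
                   cancer = if (is.null(cancer)) NA_character_ else cancer,
                   edges = data.frame(tf = character(), gene = character(),
                                      rp = numeric(), rho = numeric(),
                                      bp = numeric())))
    }
    codes <- unique(df$cancer)
    if (length(codes) > 1L)
        stop("domain error: edges span cancer types ",
             paste(codes, collapse = ", "),
             "; build one network per cancer")
    if (!is.null(cancer) && !identical(cancer, codes))
        stop("domain error: edges belong to ", codes, ", not ", cancer)
    if (!"bp" %in% colnames(df)) df$bp <- df$rp * df$rho
    out <- df[, c("tf", "gene", "rp", "rho", "bp")]
    rownames(out) <- NULL
    new("BipartiteNetwork", cancer = codes, edges = out)
}

#' Project a bipartite network onto its TF nodes
#'
#' Two TFs are connected iff they share at least one glycogene target; the
#' edge weight is the number of shared targets. All TF nodes are kept
#' (TFs with no shared target remain isolated vertices), in sorted name
#' order for determinism.
#'
#' @param network a [BipartiteNetwork-class].
#' @return an undirected \pkg{igraph} graph with integer edge attribute
#'   \code{weight}.
#' @export
projectTFGraph <- function(network) {
    stopifnot(is(network, "BipartiteNetwork"))
    tfs <- tfNodes(network)
    genes <- geneNodes(network)
    if (length(tfs) == 0L)
        return(igraph::make_empty_graph(0, directed = FALSE))
    df <- network@edges
    M <- matrix(0L, length(tfs), length(genes),
                dimnames = list(tfs, genes))
    M[cbind(match(df$tf, tfs), match(df$gene, genes))] <- 1L
    W <- M %*% t(M)
    diag(W) <- 0L
    g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                             weighted = TRUE)
    g
}

.membershipVector <- function(graph, partition) {
    nm <- igraph::V(graph)$name
    if (!is.null(names(partition)) && !is.null(nm)) {
        if (!setequal(names(partition), nm) ||
            length(partition) != length(nm))
            stop("domain error: partition must cover every node exactly once")
        partition <- partition[nm]
    } else if (length(partition) != igraph::vcount(graph)) {
        stop("domain error: partition must cover every node exactly once")
    }
    if (any(is.na(partition)))
        stop("domain error: partition must cover every node exactly once")
    as.integer(factor(partition))
}

#' Weighted modularity of a partition
#'
#' Newman-Girvan modularity
#' \deqn{Q = \frac{1}{2m}\sum_{ij}\left[A_{ij} - \frac{k_i k_j}{2m}\right]
#'   \delta(c_i, c_j)}
#' with weighted adjacency \eqn{A}, weighted degrees \eqn{k} and total edge
#' weight \eqn{m}.
#'
#' @param graph an undirected \pkg{igraph} graph, optionally with a
#'   \code{weight} edge attribute (unit weights otherwise).
#' @param partition community labels, either in vertex order or named by
#'   vertex name; must cover all nodes.
#' @return modularity Q in \[-0.5, 1).
#' @export
modularityQ <- function(graph, partition) {
    mem <- .membershipVector(graph, partition)
    w <- if ("weight" %in% igraph::edge_attr_names(graph))
             igraph::E(graph)$weight else rep(1, igraph::ecount(graph))
    m <- sum(w)
    if (m == 0) return(0)
    ends <- igraph::ends(graph, igraph::E(graph), names = FALSE)
    k <- igraph::strength(graph, weights = w)
    within <- sum(w[mem[ends[, 1L]] == mem[ends[, 2L]]])
    ktot <- tapply(k, mem, sum)
    within / m - sum((ktot / (2 * m))^2)
}

#' Greedy modularity communities (CNM agglomeration)
#'
#' Deterministic Clauset-Newman-Moore agglomeration: starting from
#' singleton communities, repeatedly merges the connected community pair
#' with the largest modularity gain (ties broken by the lexicographically
#' smallest community-id pair, ids being the smallest original vertex
#' index in each community) and returns the partition with maximal
#' modularity along the merge path. Identical graphs always yield
#' identical partitions.
#'
#' @param graph an undirected \pkg{igraph} graph, optionally weighted.
#' @return integer community membership named by vertex name, with the
#'   achieved modularity in attribute \code{"modularity"}.
#' @export
greedyModularityCommunities <- function(graph) {
    n <- igraph::vcount(graph)
    if (n == 0L) stop("empty graph")
    nm <- igraph::V(graph)$name
    if (is.null(nm)) nm <- as.character(seq_len(n))
    w <- if ("weight" %in% igraph::edge_attr_names(graph))
             igraph::E(graph)$weight else rep(1, igraph::ecount(graph))
    m <- sum(w)
    if (m == 0) {
        out <- seq_len(n)
        names(out) <- nm
        attr(out, "modularity") <- 0
        return(out)
    }
    A <- matrix(0, n, n)
    ends <- igraph::ends(graph, igraph::E(graph), names = FALSE)
    # accumulate parallel edges if any
    for (e in seq_along(w)) {
        i <- ends[e, 1L]; j <- ends[e, 2L]
        A[i, j] <- A[i, j] + w[e]
        if (i != j) A[j, i] <- A[j, i] + w[e]
    }
    E <- A / (2 * m)          # community-by-community edge weight fractions
    a <- rowSums(E)           # degree fractions
    comm <- seq_len(n)        # representative id per node
    active <- rep(TRUE, n)
    Q <- sum(diag(E)) - sum(a^2)
    bestQ <- Q
    bestComm <- comm
    eps <- 1e-12
    while (sum(active) > 1L) {
        idx <- which(active)
        sub <- E[idx, idx, drop = FALSE]
        diag(sub) <- 0
        conn <- which(sub > 0, arr.ind = TRUE)
        conn <- conn[conn[, 1L] < conn[, 2L], , drop = FALSE]
        if (nrow(conn) == 0L) break   # only disconnected parts remain
        i <- idx[conn[, 1L]]; j <- idx[conn[, 2L]]
        dq <- 2 * (E[cbind(i, j)] - a[i] * a[j])
        top <- which(dq >= max(dq) - eps)
        # lexicographically smallest (i, j) among ties
        top <- top[order(i[top], j[top])][1L]
        ii <- i[top]; jj <- j[top]
        # merge jj into ii (ii < jj by construction of representatives)
        newDiag <- E[ii, ii] + E[jj, jj] + 2 * E[ii, jj]
        E[ii, ] <- E[ii, ] + E[jj, ]
        E[, ii] <- E[, ii] + E[, jj]
        E[ii, ii] <- newDiag
        E[jj, ] <- 0
        E[, jj] <- 0
        a[ii] <- a[ii] + a[jj]
        a[jj] <- 0
        active[jj] <- FALSE
        comm[comm == jj] <- ii
        Q <- Q + dq[top]
        if (Q > bestQ + eps) {
            bestQ <- Q
            bestComm <- comm
        }
    }
    out <- as.integer(factor(bestComm, levels = unique(bestComm)))
    names(out) <- nm
    attr(out, "modularity") <- bestQ
    out
}

#' Assign glycogenes to TF communities
#'
#' Builds a [TFCommunitySet-class] from a TF partition: each glycogene is
#' assigned to the community holding the plurality of its regulating TFs;
#' ties go to the community with the larger total binding potential toward
#' that gene, and residual ties to the smaller community id. Community ids
#' are renumbered 1-based in decreasing TF-count order (ties by smallest
#' member name).
#'
#' @param partition TF community membership as returned by
#'   [greedyModularityCommunities()] (named integer vector over the
#'   network's TF nodes).
#' @param network the [BipartiteNetwork-class] the partition belongs to.
#' @return a [TFCommunitySet-class].
#' @export
assignGlycogenes <- function(partition, network) {
    stopifnot(is(network, "BipartiteNetwork"))
    tfs <- tfNodes(network)
    if (!setequal(names(partition), tfs))
        stop("domain error: partition must cover the network's TF nodes")
    Q <- attr(partition, "modularity")
    if (is.null(Q)) {
        g <- projectTFGraph(network)
        Q <- modularityQ(g, partition)
    }
    # renumber: 1-based ids in decreasing community size order
    sizes <- table(partition)
    firstMember <- vapply(names(sizes), function(cid)
        min(names(partition)[partition == cid]), "")
    ord <- order(-as.integer(sizes), firstMember)
    newId <- seq_along(ord)
    names(newId) <- names(sizes)[ord]
    tfComm <- newId[as.character(partition)]
    names(tfComm) <- names(partition)
    df <- network@edges
    geneComm <- vapply(geneNodes(network), function(g) {
        sub <- df[df$gene == g, , drop = FALSE]
        comms <- tfComm[sub$tf]
        votes <- table(comms)
        top <- names(votes)[votes == max(votes)]
        if (length(top) > 1L) {
            bp <- vapply(top, function(cid)
                sum(sub$bp[comms == as.integer(cid)]), 0)
            top <- top[bp == max(bp)]
        }
        min(as.integer(top))
    }, 0L)
    membership <- rbind(
        data.frame(node = names(tfComm), type = "TF",
                   community = as.integer(tfComm),
                   stringsAsFactors = FALSE),
        data.frame(node = names(geneComm), type = "glycogene",
                   community = as.integer(geneComm),
                   stringsAsFactors = FALSE))
    rownames(membership) <- NULL
    new("TFCommunitySet", cancer = network@cancer,
        membership = membership, modularity = as.numeric(Q))
}

#' Glycopathway overrepresentation within TF communities
#'
#' For each requested community, tests every glycosylation pathway for
#' overrepresentation among the community's edges (the retained edges
#' whose TF belongs to the community) relative to all retained edges of
#' the cancer, with the one-sided hypergeometric tail; BH adjustment is
#' applied across all tests of the call.
#'
#' @param communitySet a [TFCommunitySet-class].
#' @param edges the retained edges of the same cancer ([TFGeneTable-class],
#'   [BipartiteNetwork-class] or data.frame).
#' @param classification a [PathwayClassification-class].
#' @param ids community ids to test (default: all).
#' @return a [S4Vectors::DataFrame] with columns \code{community},
#'   \code{pathway}, \code{k}, \code{n}, \code{K}, \code{N}, \code{p},
#'   \code{pAdj}.
#' @export
communityGlycoEnrichment <- function(communitySet, edges, classification,
                                     ids = NULL) {
    stopifnot(is(communitySet, "TFCommunitySet"))
    df <- .edgeFrame(edges)
    mem <- communitySet@membership
    tfComm <- mem[mem$type == "TF", , drop = FALSE]
    if (is.null(ids)) ids <- sort(unique(tfComm$community))
    pathways <- .pathwayList(classification)
    N <- nrow(df)
    res <- lapply(ids, function(cid) {
        inComm <- df$tf %in% tfComm$node[tfComm$community == cid]
        n <- sum(inComm)
        if (n == 0L) return(NULL)
        do.call(rbind, lapply(names(pathways), function(pw) {
            inP <- df$gene %in% pathways[[pw]]
            data.frame(community = cid, pathway = pw,
                       k = sum(inComm & inP), n = n,
                       K = sum(inP), N = N, stringsAsFactors = FALSE)
        }))
    })
    res <- do.call(rbind, res)
    if (is.null(res))
        return(DataFrame(community = integer(), pathway = character(),
                         k = integer(), n = integer(), K = integer(),
                         N = integer(), p = numeric(), pAdj = numeric()))
    res$p <- hypergeometricTail(res$k, res$K, res$n, res$N)
    res$pAdj <- benjaminiHochberg(res$p)
    rownames(res) <- NULL
    DataFrame(res)
}

.bipartiteIgraph <- function(network, communitySet = NULL) {
    tfs <- tfNodes(network)
    genes <- geneNodes(network)
    nodes <- data.frame(name = c(tfs, genes),
                        type = c(rep("TF", length(tfs)),
                                 rep("glycogene", length(genes))),
                        stringsAsFactors = FALSE)
    if (!is.null(communitySet)) {
        mem <- communitySet@membership
        nodes$community <- mem$community[match(nodes$name, mem$node)]
    }
    df <- network@edges
    edges <- data.frame(from = df$tf, to = df$gene, rp = df$rp,
                        rho = df$rho, bp = df$bp, weight = df$bp,
                        stringsAsFactors = FALSE)
    igraph::graph_from_data_frame(edges, directed = FALSE,
                                  vertices = nodes)
}

#' Export a bipartite network as GraphML
#'
#' Writes a Cytoscape-loadable GraphML file with node attributes
#' \code{type} ("TF"/"glycogene") and, when a community set is supplied,
#' \code{community}; edge attributes are \code{rp}, \code{rho}, \code{bp}
#' and \code{weight} (= bp, for layout weighting).
#'
#' @param network a [BipartiteNetwork-class].
#' @param path output file path.
#' @param communitySet optional [TFCommunitySet-class] for node community
#'   ids.
#' @return \code{path}, invisibly.
#' @export
exportGraphML <- function(network, path, communitySet = NULL) {
    g <- .bipartiteIgraph(network, communitySet)
    igraph::write_graph(g, path, format = "graphml")
    invisible(path)
}

#' Export a bipartite network as SIF
#'
#' Simple interaction format: one \code{tf regulates gene} line per edge,
#' tab-separated, in deterministic (tf, gene) order.
#'
#' @param network a [BipartiteNetwork-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
exportSIF <- function(network, path) {
    df <- network@edges
    df <- df[order(df$tf, df$gene), , drop = FALSE]
    writeLines(paste(df$tf, "regulates", df$gene, sep = "\t"), path)
    invisible(path)
}

#' Write a community membership table
#'
#' Tab-separated table with columns \code{cancer}, \code{node},
#' \code{type}, \code{community}.
#'
#' @param communitySet a [TFCommunitySet-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeCommunityTable <- function(communitySet, path) {
    mem <- communitySet@membership
    out <- data.frame(cancer = communitySet@cancer, mem,
                      stringsAsFactors = FALSE)
    out <- out[order(out$type, out$node), , drop = FALSE]
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
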