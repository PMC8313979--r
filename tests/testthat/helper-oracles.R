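# Independent oracles and tiny fixture builders used across the suite.

# Exhaustive hypergeometric upper tail: enumerate all C(N, n) draws from a
# population of N items containing K successes; count draws with >= k hits.
enumTail <- function(k, K, n, N) {
    pop <- c(rep(1L, K), rep(0L, N - K))
    draws <- utils::combn(N, n)
    hits <- apply(draws, 2L, function(ix) sum(pop[ix]))
    mean(hits >= k)
}

# All set partitions of 1..n as restricted-growth strings.
allPartitions <- function(n) {
    out <- list()
    grow <- function(labels, maxLab) {
        i <- length(labels) + 1L
        if (i > n) {
            out[[length(out) + 1L]] <<- labels
            return(invisible())
        }
        for (lab in seq_len(maxLab + 1L))
            grow(c(labels, lab), max(maxLab, lab))
    }
    grow(integer(), 0L)
    out
}

# Brute-force maximum modularity over every partition of the graph's nodes,
# evaluated directly from the weighted adjacency matrix (independent of the
# package's modularity code).
bruteForceMaxQ <- function(graph) {
    n <- igraph::vcount(graph)
    A <- igraph::as_adjacency_matrix(graph, attr = if ("weight" %in%
        igraph::edge_attr_names(graph)) "weight" else NULL, sparse = FALSE)
    m2 <- sum(A)                       # 2m
    if (m2 == 0) return(0)
    k <- rowSums(A)
    qOf <- function(p) {
        same <- outer(p, p, "==")
        (sum(A[same]) - sum(outer(k, k)[same]) / m2) / m2
    }
    max(vapply(allPartitions(n), qOf, 0))
}

# Random weighted graph in the style of a shared-target TF projection:
# integer weights, moderate density, named vertices.
randomTFGraph <- function(n, p = 0.5, wmax = 5) {
    A <- matrix(0L, n, n)
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
        if (stats::runif(1) < p)
            A[i, j] <- A[j, i] <- sample.int(wmax, 1L)
    }
    dimnames(A) <- list(sprintf("TF%02d", 1:n), sprintf("TF%02d", 1:n))
    igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                        weighted = TRUE)
}

# Random bipartite edge table for one cancer.
randomBipartiteEdges <- function(nTF = 6, nGene = 10, p = 0.4,
                                 cancer = "CAN_01") {
    grid <- expand.grid(tf = sprintf("TF%02d", seq_len(nTF)),
                        gene = sprintf("G%02d", seq_len(nGene)),
                        stringsAsFactors = FALSE)
    grid <- grid[stats::runif(nrow(grid)) < p, , drop = FALSE]
    grid$cancer <- cancer
    grid$rp <- stats::runif(nrow(grid))
    grid$rho <- stats::runif(nrow(grid), -1, 1)
    grid$bp <- grid$rp * grid$rho
    rownames(grid) <- NULL
    grid
}

writeTempTSV <- function(lines) {
    path <- tempfile(fileext = ".tsv")
    writeLines(lines, path)
    path
}

smallTable <- function(rows) {
    # rows: list of c(tf, gene, cancer, rp, rho)
    df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    colnames(df) <- c("tf", "gene", "cancer", "rp", "rho")
    df$rp <- as.numeric(df$rp); df$rho <- as.numeric(df$rho)
    df$bp <- df$rp * df$rho
    new("TFGeneTable", records = df)
}
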