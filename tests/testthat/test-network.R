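twoTriangles <- function() {
    A <- matrix(0, 6, 6, dimnames = list(letters[1:6], letters[1:6]))
    for (e in list(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6)))
        A[e[1], e[2]] <- A[e[2], e[1]] <- 1
    igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                        weighted = TRUE)
}

test_that("bipartite networks mirror their input edges", {
    tab <- smallTable(list(
        c("T1", "g1", "C1", 0.9, 0.5), c("T1", "g2", "C1", 0.8, 0.5),
        c("T2", "g2", "C1", 0.7, 0.5), c("T2", "g3", "C1", 0.6, 0.5)))
    net <- buildBipartite(tab)
    expect_equal(length(tfNodes(net)) + length(geneNodes(net)), 5L)
    expect_equal(nrow(networkEdges(net)), 4L)
    expect_equal(tfNodes(net), c("T1", "T2"))
    # node counts equal unique symbol counts of the input
    set.seed(9)
    df <- randomBipartiteEdges(7, 12, 0.4)
    net2 <- buildBipartite(df)
    expect_equal(length(tfNodes(net2)), length(unique(df$tf)))
    expect_equal(length(geneNodes(net2)), length(unique(df$gene)))
    # mixed cancer codes are a domain error
    mixed <- smallTable(list(c("T1", "g1", "C1", 0.9, 0.5),
                             c("T1", "g1", "C2", 0.9, 0.5)))
    expect_error(buildBipartite(mixed), "cancer")
    # empty input gives an empty network
    empty <- buildBipartite(records(tab)[0, ], cancer = "C9")
    expect_equal(nrow(networkEdges(empty)), 0L)
})

test_that("TF projection counts shared targets", {
    tab <- smallTable(list(
        c("TF1", "g1", "C1", 0.9, 0.5), c("TF1", "g2", "C1", 0.9, 0.5),
        c("TF1", "g3", "C1", 0.9, 0.5), c("TF2", "g2", "C1", 0.9, 0.5),
        c("TF2", "g3", "C1", 0.9, 0.5), c("TF2", "g4", "C1", 0.9, 0.5),
        c("TF3", "g9", "C1", 0.9, 0.5)))
    g <- projectTFGraph(buildBipartite(tab))
    expect_equal(igraph::vcount(g), 3L)   # isolated TF3 kept
    w <- igraph::E(g)$weight[igraph::get_edge_ids(g, c("TF1", "TF2"))]
    expect_equal(w, 2)
    expect_equal(igraph::degree(g)[["TF3"]], 0)
    # double-counting identity: sum of pair weights = sum_g C(deg(g), 2)
    set.seed(13)
    for (i in 1:5) {
        df <- randomBipartiteEdges(8, 14, 0.35)
        net <- buildBipartite(df)
        gg <- projectTFGraph(net)
        lhs <- sum(igraph::E(gg)$weight)
        deg <- table(df$gene)
        rhs <- sum(choose(deg, 2))
        expect_equal(lhs, rhs)
    }
})

test_that("modularity matches hand-derived values and igraph", {
    g <- twoTriangles()
    # single all-inclusive community
    expect_equal(modularityQ(g, rep(1, 6)), 0)
    # the two components
    expect_equal(modularityQ(g, c(1, 1, 1, 2, 2, 2)), 0.5)
    # all singletons: -sum(k_i^2) / (2m)^2
    expect_equal(modularityQ(g, 1:6), -sum(rep(2, 6)^2) / 144)
    expect_error(modularityQ(g, c(1, 1)), "partition")
    # agreement with igraph's implementation on random weighted graphs
    set.seed(31)
    for (i in 1:10) {
        gr <- randomTFGraph(sample(4:8, 1))
        part <- sample(1:3, igraph::vcount(gr), replace = TRUE)
        expect_equal(modularityQ(gr, part),
                     igraph::modularity(gr, part,
                                        weights = igraph::E(gr)$weight),
                     tolerance = 1e-12)
    }
})

test_that("greedy agglomeration recovers exact structure on small graphs", {
    g <- twoTriangles()
    part <- greedyModularityCommunities(g)
    expect_equal(attr(part, "modularity"), 0.5)
    expect_equal(length(unique(part)), 2L)
    expect_equal(unname(part[1:3]), rep(part[["a"]], 3))
    expect_equal(unname(part[4:6]), rep(part[["d"]], 3))
    # complete graph: a single community, Q = 0
    k4 <- igraph::make_full_graph(4)
    igraph::V(k4)$name <- letters[1:4]
    p4 <- greedyModularityCommunities(k4)
    expect_equal(length(unique(p4)), 1L)
    expect_equal(attr(p4, "modularity"), 0)
    # deterministic across repeated runs
    set.seed(2)
    gr <- randomTFGraph(7)
    expect_identical(greedyModularityCommunities(gr),
                     greedyModularityCommunities(gr))
})

test_that("greedy partitions dominate the trivial partitions", {
    set.seed(8)
    for (i in 1:20) {
        gr <- randomTFGraph(sample(3:6, 1), p = 0.5)
        part <- greedyModularityCommunities(gr)
        q <- attr(part, "modularity")
        # reported Q is the true Q of the returned partition
        expect_equal(q, modularityQ(gr, part), tolerance = 1e-10)
        # never worse than all-singletons or all-in-one
        n <- igraph::vcount(gr)
        expect_gte(q, modularityQ(gr, seq_len(n)) - 1e-10)
        expect_gte(q, modularityQ(gr, rep(1, n)) - 1e-10)
    }
})

test_that("planted block structure is recovered from the projection", {
    cfg <- syntheticConfig(nCancers = 1, nTFs = 24, nGenes = 90,
                           backgroundEdgeProb = 0.01, tfActivity = 1,
                           plantedBlocks = list(
                               list(tfs = 1:8, genes = 1:25, prob = 0.8),
                               list(tfs = 9:16, genes = 31:55, prob = 0.8),
                               list(tfs = 17:24, genes = 61:85, prob = 0.8)),
                           seed = 41)
    tr <- generateSynthetic(cfg)
    net <- buildBipartite(filterRecords(tr@table))
    part <- greedyModularityCommunities(projectTFGraph(net))
    cs <- assignGlycogenes(part, net)
    rep <- recoveryReport(tr, communitySet = cs)
    expect_equal(rep$blockExact, 1)
    expect_equal(rep$blockRand, 1)
})

test_that("glycogenes join communities by plurality with BP tie-break", {
    tab <- smallTable(list(
        # community 1: T1, T2 share two targets; community 2: T3, T4
        c("T1", "s1", "C1", 0.9, 0.9), c("T2", "s1", "C1", 0.9, 0.9),
        c("T1", "s2", "C1", 0.9, 0.9), c("T2", "s2", "C1", 0.9, 0.9),
        c("T3", "s3", "C1", 0.9, 0.9), c("T4", "s3", "C1", 0.9, 0.9),
        c("T3", "s4", "C1", 0.9, 0.9), c("T4", "s4", "C1", 0.9, 0.9),
        # gene voted 2:1 into community of T1/T2
        c("T1", "gv", "C1", 0.9, 0.9), c("T2", "gv", "C1", 0.9, 0.9),
        c("T3", "gv", "C1", 0.9, 0.9),
        # tie 1:1, decided by larger BP toward the gene (T3 side wins)
        c("T1", "gt", "C1", 0.5, 0.4), c("T3", "gt", "C1", 0.9, 0.9),
        # single regulator
        c("T4", "gs", "C1", 0.9, 0.9)))
    net <- buildBipartite(tab)
    part <- greedyModularityCommunities(projectTFGraph(net))
    cs <- assignGlycogenes(part, net)
    mem <- communities(cs)
    tfOf <- function(x) mem$community[mem$node == x & mem$type == "TF"]
    geneOf <- function(x) mem$community[mem$node == x &
                                        mem$type == "glycogene"]
    expect_equal(geneOf("gv"), tfOf("T1"))
    expect_equal(geneOf("gt"), tfOf("T3"))
    expect_equal(geneOf("gs"), tfOf("T4"))
    # every gene lands in exactly one community
    expect_equal(sum(mem$type == "glycogene"), length(geneNodes(net)))
    # ids are 1-based in decreasing size order
    sizes <- table(mem$community[mem$type == "TF"])
    expect_equal(as.integer(names(sizes)), seq_along(sizes))
    expect_true(all(diff(as.integer(sizes)) <= 0))
})

test_that("community glyco-enrichment degenerates correctly", {
    tab <- smallTable(list(
        c("T1", "g1", "C1", 0.9, 0.9), c("T1", "g2", "C1", 0.9, 0.9),
        c("T2", "g1", "C1", 0.9, 0.9), c("T2", "g3", "C1", 0.9, 0.9)))
    cls <- readPathwayClassification(writeTempTSV(c("g1\tP1", "g2\tP2")))
    net <- buildBipartite(tab)
    # a community containing all edges can show no disproportion
    all1 <- stats::setNames(c(1L, 1L), c("T1", "T2"))
    attr(all1, "modularity") <- 0
    cs <- assignGlycogenes(all1, net)
    res <- as.data.frame(communityGlycoEnrichment(cs, tab, cls))
    expect_true(all(res$p == 1))
    # a community holding every edge of one pathway ranks it first
    tab2 <- smallTable(list(
        c("T1", "g1", "C1", 0.9, 0.9), c("T1", "g2", "C1", 0.9, 0.9),
        c("T2", "x1", "C1", 0.9, 0.9), c("T2", "x2", "C1", 0.9, 0.9),
        c("T2", "x3", "C1", 0.9, 0.9)))
    cls2 <- readPathwayClassification(writeTempTSV(
        c("g1\tPP", "g2\tPP", "x1\tQQ", "x2\tQQ", "x3\tQQ")))
    net2 <- buildBipartite(tab2)
    split2 <- stats::setNames(c(1L, 2L), c("T1", "T2"))
    attr(split2, "modularity") <- 0
    cs2 <- assignGlycogenes(split2, net2)
    res2 <- as.data.frame(communityGlycoEnrichment(cs2, tab2, cls2))
    comm1 <- res2[res2$community == unique(
        communities(cs2)$community[communities(cs2)$node == "T1"]), ]
    expect_equal(comm1$pathway[which.min(comm1$p)], "PP")
})

test_that("GraphML, SIF and membership exports are schema-valid", {
    set.seed(19)
    df <- randomBipartiteEdges(5, 9, 0.5)
    net <- buildBipartite(df)
    part <- greedyModularityCommunities(projectTFGraph(net))
    cs <- assignGlycogenes(part, net)
    gml <- tempfile(fileext = ".graphml")
    exportGraphML(net, gml, cs)
    back <- igraph::read_graph(gml, format = "graphml")
    expect_equal(igraph::vcount(back),
                 length(tfNodes(net)) + length(geneNodes(net)))
    expect_equal(igraph::ecount(back), nrow(networkEdges(net)))
    expect_setequal(unique(igraph::V(back)$type), c("TF", "glycogene"))
    expect_true(all(c("rp", "rho", "bp", "weight") %in%
                    igraph::edge_attr_names(back)))
    sif <- tempfile(fileext = ".sif")
    exportSIF(net, sif)
    lines <- readLines(sif)
    expect_length(lines, nrow(networkEdges(net)))
    expect_true(all(grepl("\tregulates\t", lines)))
    tsv <- tempfile(fileext = ".tsv")
    writeCommunityTable(cs, tsv)
    mem <- utils::read.delim(tsv)
    expect_setequal(colnames(mem), c("cancer", "node", "type", "community"))
})
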