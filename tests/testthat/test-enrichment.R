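test_that("hypergeometric tail matches closed forms and enumeration", {
    expect_equal(hypergeometricTail(3, 5, 4, 10), 55 / 210)
    expect_equal(hypergeometricTail(2, 2, 2, 10), 1 / 45)
    # k = 0 covers the whole upper tail
    expect_equal(hypergeometricTail(0, 5, 4, 10), 1)
    expect_equal(hypergeometricTail(0, 0, 3, 8), 1)
    # spot-check exhaustive enumeration on small margins
    set.seed(7)
    for (i in 1:25) {
        N <- sample(3:10, 1); K <- sample(0:N, 1); n <- sample(1:N, 1)
        k <- sample(0:min(K, n), 1)
        expect_equal(hypergeometricTail(k, K, n, N), enumTail(k, K, n, N),
                     tolerance = 1e-12)
    }
    # monotone decreasing in k while margins stay fixed
    p <- hypergeometricTail(0:4, 6, 4, 12)
    expect_true(all(diff(p) <= 0))
    expect_error(hypergeometricTail(3, 2, 2, 10), "domain")
    expect_error(hypergeometricTail(1, 11, 2, 10), "domain")
})

test_that("the tail probability equals one-sided Fisher on 2x2 tables", {
    set.seed(11)
    for (i in 1:20) {
        a <- sample(0:5, 1); b <- sample(0:6, 1)
        cc <- sample(0:6, 1); d <- sample(0:8, 1)
        if (a + b == 0 || a + cc == 0 || a + b + cc + d == 0) next
        p <- hypergeometricTail(a, a + cc, a + b, a + b + cc + d)
        ft <- stats::fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE),
                                 alternative = "greater")$p.value
        expect_equal(p, ft, tolerance = 1e-10)
    }
})

test_that("contingency tables count edges in and out of a pathway", {
    cls <- readPathwayClassification(writeTempTSV(
        c("g1\tP", "g9\tP")))
    edges <- smallTable(list(
        c("X", "g1", "C1", 0.9, 0.5), c("X", "g2", "C1", 0.9, 0.5),
        c("Y", "g9", "C1", 0.9, 0.5), c("Y", "g3", "C1", 0.9, 0.5),
        c("Z", "g4", "C1", 0.9, 0.5), c("Z", "g5", "C1", 0.9, 0.5)))
    tab <- buildContingency("X", "P", edges, cls)
    expect_equal(tab, c(a = 1L, b = 1L, c = 1L, d = 3L))
    # a TF whose every target is unclassified gets a = 0
    expect_equal(buildContingency("Z", "P", edges, cls)[["a"]], 0L)
    expect_error(buildContingency("missing", "P", edges, cls), "domain")
    mixed <- smallTable(list(c("X", "g1", "C1", 0.9, 0.5),
                             c("X", "g1", "C2", 0.9, 0.5)))
    expect_error(buildContingency("X", "P", mixed, cls), "one cancer")
    # margin identity on a random fixture: a+b+c+d = total edges
    set.seed(5)
    df <- randomBipartiteEdges(8, 15, 0.5)
    rnd <- new("TFGeneTable",
               records = df[, c("tf", "gene", "cancer", "rp", "rho", "bp")])
    cls2 <- readPathwayClassification(writeTempTSV(
        sprintf("G%02d\tPW", 1:6)))
    for (tf in unique(df$tf)) {
        tb <- buildContingency(tf, "PW", rnd, cls2)
        expect_equal(sum(tb), nrow(df))
        expect_equal(tb[["a"]] + tb[["b"]], sum(df$tf == tf))
    }
})

test_that("BH adjustment follows the step-up rule", {
    expect_equal(benjaminiHochberg(c(0.01, 0.02, 0.03, 0.04)),
                 rep(0.04, 4))
    expect_equal(benjaminiHochberg(0.37), 0.37)           # m = 1
    expect_equal(benjaminiHochberg(rep(0.2, 5)), rep(0.2, 5))
    # independent hand-rolled step-up oracle on random vectors
    bhOracle <- function(p) {
        m <- length(p); o <- order(p); adj <- numeric(m)
        sorted <- p[o]
        running <- 1
        for (i in m:1) {
            running <- min(running, m * sorted[i] / i)
            adj[i] <- running
        }
        adj[order(o)]
    }
    set.seed(21)
    for (i in 1:20) {
        p <- runif(sample(1:40, 1))
        expect_equal(benjaminiHochberg(p), bhOracle(p), tolerance = 1e-12)
    }
    expect_error(benjaminiHochberg(c(0.5, 1.2)), "domain")
})

test_that("per-cancer TF-pathway enrichment finds a planted signal", {
    # one TF whose 10 edges all hit one 10-gene pathway in a 110-edge table
    set.seed(3)
    rows <- list()
    for (g in 1:10)
        rows[[length(rows) + 1]] <-
            c("HOT", sprintf("P%02d", g), "C1", 0.9, 0.8)
    for (i in 1:100)
        rows[[length(rows) + 1]] <-
            c(sprintf("T%02d", (i %% 20) + 1), sprintf("B%03d", i), "C1",
              0.9, 0.8)
    tab <- smallTable(rows)
    cls <- readPathwayClassification(writeTempTSV(
        c(sprintf("P%02d\tpathway1", 1:10), sprintf("B%03d\tpathway2", 1:10))))
    res <- as.data.frame(enrichTFPathways(tab, cls))
    best <- res[which.min(res$p), ]
    expect_equal(best$tf, "HOT")
    expect_equal(best$pathway, "pathway1")
    expect_equal(best$a, 10L)
    # a TF with zero edges in a pathway has p = 1 and is not flagged
    zero <- res[res$tf == "T01" & res$pathway == "pathway1", ]
    expect_equal(zero$p, 1)
    expect_false(zero$significant)
    # counts agree with buildContingency
    tb <- buildContingency("HOT", "pathway1", tab, cls)
    expect_equal(unname(unlist(best[c("a", "b", "c", "d")])), unname(tb))
})

test_that("BH scope pools globally by default or within cancers", {
    tab <- smallTable(list(
        c("A", "g1", "C1", 0.9, 0.8), c("A", "g2", "C1", 0.9, 0.8),
        c("B", "g3", "C1", 0.9, 0.8),
        c("A", "g1", "C2", 0.9, 0.8), c("C", "g4", "C2", 0.9, 0.8)))
    cls <- readPathwayClassification(writeTempTSV(c("g1\tP", "g2\tP")))
    glob <- as.data.frame(enrichTFPathways(tab, cls, bhScope = "global"))
    per <- as.data.frame(enrichTFPathways(tab, cls, bhScope = "per_cancer"))
    expect_equal(glob$p, per$p)   # raw p identical, only pooling differs
    expect_equal(glob$pAdj, benjaminiHochberg(glob$p))
    for (cc in unique(per$cancer)) {
        i <- per$cancer == cc
        expect_equal(per$pAdj[i], benjaminiHochberg(per$p[i]))
    }
    expect_true(all(glob$pAdj >= glob$p))
    # restricting the background to classified genes changes margins only
    resC <- as.data.frame(enrichTFPathways(tab, cls,
                                           backgroundClassifiedOnly = TRUE))
    expect_true(all(resC$a + resC$b + resC$c + resC$d <=
                    glob$a[1] + glob$b[1] + glob$c[1] + glob$d[1]))
})

test_that("null enrichment p-values are conservative under label permutation", {
    # permuting gene -> pathway labels gives a raw-p distribution that is
    # stochastically >= uniform (discrete one-sided tests are conservative)
    set.seed(17)
    cfg <- syntheticConfig(nCancers = 1, nTFs = 30, nGenes = 120,
                           pathwaySize = 10, tfActivity = 1, seed = 17)
    tr <- generateSynthetic(cfg)
    filt <- filterRecords(tr@table)
    mem <- records(tr@classification)
    mem$gene <- sample(mem$gene)   # uniform label permutation
    mem <- unique(mem)
    cls <- new("PathwayClassification", membership = mem)
    res <- as.data.frame(enrichTFPathways(filt, cls))
    flagged <- mean(res$p <= 0.05)
    expect_lte(flagged, 0.08)
    # one-sided KS direction: empirical CDF of p never exceeds uniform by much
    expect_lte(max(stats::ecdf(res$p)(seq(0.05, 0.95, 0.05)) -
                   seq(0.05, 0.95, 0.05)), 0.05)
})

test_that("degree of regulation sums -log10 adjusted p over significant TFs", {
    res <- data.frame(cancer = "C1",
                      tf = c("A", "B", "C"),
                      pathway = "P",
                      pAdj = c(0.01, 0.001, 0.5))
    d <- as.data.frame(degreeOfRegulation(res))
    expect_equal(d$nTFs, 2L)
    expect_equal(d$degree, 5)          # 2 + 3 exactly
    # no significant TFs: (0, 0)
    none <- data.frame(cancer = "C1", tf = "A", pathway = "P", pAdj = 0.9)
    d0 <- as.data.frame(degreeOfRegulation(none))
    expect_equal(d0$nTFs, 0L)
    expect_equal(d0$degree, 0)
    expect_true(all(as.data.frame(degreeOfRegulation(res))$degree >= 0))
})
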