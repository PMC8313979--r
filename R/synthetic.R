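#' Configuration for the synthetic Cistrome-like generator
#'
#' Assembles and validates the parameters of [generateSynthetic()]. The
#' defaults emulate the statistical structure of the real mining setting:
#' 570 TFs, 341 glycogenes and 29 cancer types; about half of the TFs
#' active per cancer type; a background edge density chosen so an active
#' TF regulates on the order of three glycogenes after RP/rho filtering
#' (with per-TF counts ranging from roughly 1 to 10); and roughly 61% of
#' genes classified into 20 pathways of 10 genes each. Regulatory edges
#' split into genuine ("true") edges, whose RP ~ Beta(5, 2) and
#' rho ~ scaled Beta(32, 8) on \[-1, 1\] (mean 0.6) mostly survive the
#' default thresholds (per-edge pass probability ~0.83), and decoys
#' (RP ~ Beta(2, 5), rho ~ scaled Beta(2, 2), mean 0) that mostly do not
#' (~0.02). The rho concentration is the generator's calibration
#' parameter: the mean is fixed at 0.6 and the concentration is set so
#' that a strongly planted pathway (factor >= 5) is recovered at the
#' FDR-corrected level in at least 95% of replicates.
#'
#' Planted TF-pathway pairs get an edge probability into their pathway's
#' genes of \code{p + (1 - p) * (1 - exp(-(factor - 1)))} with \code{p}
#' the background probability: \code{factor = 1} reduces exactly to the
#' background (a pure null), while \code{factor >= 5} saturates the
#' pathway (the TF regulates essentially all of its genes). Planted
#' blocks are (TF group, gene group) rectangles with an elevated
#' within-block edge probability, producing TF communities.
#'
#' @param nCancers,nTFs,nGenes problem dimensions.
#' @param nPathways,pathwaySize number and size of glyco-pathways.
#' @param classifiedFraction fraction of genes eligible for classification.
#' @param backgroundEdgeProb per-(TF, gene) background edge probability.
#' @param backgroundTrueProb probability that a background edge is a
#'   genuine regulatory edge rather than a decoy.
#' @param tfActivity fraction of TFs active in each cancer type.
#' @param plantedPairs data.frame with columns \code{tf}, \code{pathway}
#'   (1-based indices), \code{factor} (>= 1) and optionally \code{cancer}
#'   (index; \code{NA} = planted in every cancer).
#' @param plantedBlocks list of blocks, each a list with integer vectors
#'   \code{tfs} and \code{genes} and optional \code{prob} (default 0.8).
#' @param rpTrue,rpDecoy,rhoTrue,rhoDecoy Beta shape pairs for the score
#'   distributions (rho Betas are scaled to \[-1, 1\]).
#' @param nSignalingSets,signalingSetSize signaling collection shape
#'   (sets of TF symbols; sizes sampled within the given range).
#' @param seed integer seed governing all randomness; per-cancer streams
#'   are derived by fixed offsets.
#' @return a validated configuration list.
#' @export
syntheticConfig <- function(nCancers = 29, nTFs = 570, nGenes = 341,
                            nPathways = 20, pathwaySize = 10,
                            classifiedFraction = 208 / 341,
                            backgroundEdgeProb = 0.016,
                            backgroundTrueProb = 0.7,
                            tfActivity = 0.5,
                            plantedPairs = NULL, plantedBlocks = NULL,
                            rpTrue = c(5, 2), rpDecoy = c(2, 5),
                            rhoTrue = c(32, 8), rhoDecoy = c(2, 2),
                            nSignalingSets = 15,
                            signalingSetSize = c(5, 25),
                            seed = 1) {
    cfg <- list(nCancers = as.integer(nCancers), nTFs = as.integer(nTFs),
                nGenes = as.integer(nGenes),
                nPathways = as.integer(nPathways),
                pathwaySize = as.integer(pathwaySize),
                classifiedFraction = classifiedFraction,
                backgroundEdgeProb = backgroundEdgeProb,
                backgroundTrueProb = backgroundTrueProb,
                tfActivity = tfActivity,
                plantedPairs = plantedPairs,
                plantedBlocks = plantedBlocks,
                rpTrue = rpTrue, rpDecoy = rpDecoy,
                rhoTrue = rhoTrue, rhoDecoy = rhoDecoy,
                nSignalingSets = as.integer(nSignalingSets),
                signalingSetSize = as.integer(signalingSetSize),
                seed = as.integer(seed))
    probs <- c(cfg$backgroundEdgeProb, cfg$backgroundTrueProb,
               cfg$tfActivity, cfg$classifiedFraction)
    if (any(probs < 0 | probs > 1))
        stop("configuration error: probabilities must lie in [0, 1]")
    if (cfg$nCancers < 1L || cfg$nTFs < 1L || cfg$nGenes < 1L)
        stop("configuration error: dimensions must be positive")
    pool <- max(1L, round(cfg$classifiedFraction * cfg$nGenes))
    if (cfg$pathwaySize > pool)
        stop("configuration error: pathwaySize exceeds the classified pool")
    if (!is.null(cfg$plantedPairs)) {
        pp <- cfg$plantedPairs
        if (!all(c("tf", "pathway", "factor") %in% colnames(pp)))
            stop("configuration error: plantedPairs needs tf, pathway, factor")
        if (any(pp$tf < 1L | pp$tf > cfg$nTFs) ||
            any(pp$pathway < 1L | pp$pathway > cfg$nPathways))
            stop("configuration error: planted pair index out of range")
        if (any(pp$factor < 1))
            stop("configuration error: enrichment factor must be >= 1")
        if (!"cancer" %in% colnames(pp)) pp$cancer <- NA_integer_
        if (any(!is.na(pp$cancer) &
                (pp$cancer < 1L | pp$cancer > cfg$nCancers)))
            stop("configuration error: planted pair cancer out of range")
        cfg$plantedPairs <- pp
    }
    if (!is.null(cfg$plantedBlocks)) {
        allTfs <- unlist(lapply(cfg$plantedBlocks, `[[`, "tfs"))
        allGenes <- unlist(lapply(cfg$plantedBlocks, `[[`, "genes"))
        if (any(allTfs < 1L | allTfs > cfg$nTFs) ||
            any(allGenes < 1L | allGenes > cfg$nGenes))
            stop("configuration error: planted block index out of range")
        if (anyDuplicated(allTfs))
            stop("configuration error: planted TF blocks must be disjoint")
    }
    cfg
}

.symbols <- function(prefix, n) sprintf("%s%03d", prefix, seq_len(n))

.rhoDraw <- function(n, shape) 2 * stats::rbeta(n, shape[1], shape[2]) - 1

#' Generate a synthetic TF-glycogene dataset with ground truth
#'
#' Draws a Cistrome-like TF-gene relationship table, a gene-to-pathway
#' classification and a signaling gene-set collection from a
#' [syntheticConfig()], with planted TF-pathway enrichments and planted
#' TF-gene co-regulation blocks recorded as ground truth. Output is
#' deterministic for a fixed seed; the RNG state of the caller is left
#' untouched.
#'
#' @param config a configuration from [syntheticConfig()].
#' @return a [SyntheticTruth-class].
#' @export
generateSynthetic <- function(config = syntheticConfig()) {
    cfg <- do.call(syntheticConfig, config)   # revalidate
    old <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    tfSym <- .symbols("TF", cfg$nTFs)
    geneSym <- .symbols("G", cfg$nGenes)
    cancerSym <- sprintf("CAN_%02d", seq_len(cfg$nCancers))
    pwSym <- sprintf("glycopathway_%02d", seq_len(cfg$nPathways))
    set.seed(cfg$seed)
    # classification over the classified pool (multi-membership arises
    # naturally when nPathways * pathwaySize exceeds the pool)
    pool <- geneSym[seq_len(max(1L, round(cfg$classifiedFraction *
                                          cfg$nGenes)))]
    classification <- do.call(rbind, lapply(seq_len(cfg$nPathways),
        function(i) data.frame(gene = sample(pool, cfg$pathwaySize),
                               pathway = pwSym[i],
                               stringsAsFactors = FALSE)))
    classification <- unique(classification)
    pathGenes <- split(classification$gene, classification$pathway)
    # signaling collection over TF symbols
    sizeRange <- seq.int(cfg$signalingSetSize[1], cfg$signalingSetSize[2])
    sizes <- pmin(sizeRange[sample.int(length(sizeRange),
                                       cfg$nSignalingSets,
                                       replace = TRUE)], cfg$nTFs)
    sets <- lapply(sizes, function(s) sort(sample(tfSym, s)))
    names(sets) <- sprintf("signaling_%02d", seq_len(cfg$nSignalingSets))
    pp <- cfg$plantedPairs
    blocks <- cfg$plantedBlocks
    mustActive <- integer()
    if (!is.null(pp)) mustActive <- c(mustActive, pp$tf)
    if (!is.null(blocks))
        mustActive <- c(mustActive, unlist(lapply(blocks, `[[`, "tfs")))
    nActive <- max(1L, round(cfg$tfActivity * cfg$nTFs))
    rows <- vector("list", cfg$nCancers)
    for (ci in seq_len(cfg$nCancers)) {
        set.seed(cfg$seed + 7919L * ci)   # fixed per-cancer offset
        active <- sort(unique(c(sample(cfg$nTFs, nActive), mustActive)))
        nA <- length(active)
        prob <- matrix(cfg$backgroundEdgeProb, nA, cfg$nGenes)
        truth <- matrix(NA, nA, cfg$nGenes)   # NA = background mixture
        if (!is.null(blocks)) {
            for (b in blocks) {
                bprob <- if (is.null(b$prob)) 0.8 else b$prob
                i <- match(b$tfs, active)
                prob[i, b$genes] <- pmax(prob[i, b$genes], bprob)
                truth[i, b$genes] <- TRUE
            }
        }
        forced <- NULL
        if (!is.null(pp)) {
            here <- pp[is.na(pp$cancer) | pp$cancer == ci, , drop = FALSE]
            for (k in seq_len(nrow(here))) {
                f <- here$factor[k]
                pBg <- cfg$backgroundEdgeProb
                pi_f <- pBg + (1 - pBg) * (1 - exp(-(f - 1)))
                gi <- match(pathGenes[[pwSym[here$pathway[k]]]], geneSym)
                i <- match(here$tf[k], active)
                prob[i, gi] <- pmax(prob[i, gi], pi_f)
                if (f > 1) {
                    truth[i, gi] <- TRUE
                    forced <- rbind(forced, c(i, min(gi)))
                }
            }
        }
        edge <- matrix(stats::runif(nA * cfg$nGenes), nA) < prob
        if (!is.null(forced)) edge[forced] <- TRUE   # >= 1 edge per pair
        isTrue <- truth
        bg <- which(is.na(isTrue))
        isTrue[bg] <- stats::runif(length(bg)) < cfg$backgroundTrueProb
        idx <- which(edge, arr.ind = TRUE)
        if (nrow(idx) == 0L) next
        tr <- isTrue[idx] == 1
        nE <- nrow(idx)
        rp <- ifelse(tr, stats::rbeta(nE, cfg$rpTrue[1], cfg$rpTrue[2]),
                     stats::rbeta(nE, cfg$rpDecoy[1], cfg$rpDecoy[2]))
        rho <- ifelse(tr, .rhoDraw(nE, cfg$rhoTrue),
                      .rhoDraw(nE, cfg$rhoDecoy))
        ord <- order(idx[, 1L], idx[, 2L])
        rows[[ci]] <- data.frame(tf = tfSym[active[idx[ord, 1L]]],
                                 gene = geneSym[idx[ord, 2L]],
                                 cancer = cancerSym[ci],
                                 rp = rp[ord], rho = rho[ord],
                                 stringsAsFactors = FALSE)
    }
    allRows <- do.call(rbind, rows)
    if (is.null(allRows))
        allRows <- data.frame(tf = character(), gene = character(),
                              cancer = character(), rp = numeric(),
                              rho = numeric(), stringsAsFactors = FALSE)
    table <- .newTFGeneTable(allRows)
    msg <- .validTFGeneRecords(table@records)
    if (!isTRUE(msg)) stop("internal generator error: ", msg)
    pairs <- if (is.null(pp)) {
        data.frame(cancer = character(), tf = character(),
                   pathway = character(), factor = numeric(),
                   stringsAsFactors = FALSE)
    } else {
        do.call(rbind, lapply(seq_len(nrow(pp)), function(k) {
            canc <- if (is.na(pp$cancer[k])) cancerSym
                    else cancerSym[pp$cancer[k]]
            data.frame(cancer = canc, tf = tfSym[pp$tf[k]],
                       pathway = pwSym[pp$pathway[k]],
                       factor = pp$factor[k], stringsAsFactors = FALSE)
        }))
    }
    blockVec <- integer()
    if (!is.null(blocks)) {
        blockVec <- unlist(lapply(seq_along(blocks), function(b)
            stats::setNames(rep(b, length(blocks[[b]]$tfs)),
                            tfSym[blocks[[b]]$tfs])))
    }
    new("SyntheticTruth", table = table,
        classification = new("PathwayClassification",
                             membership = classification),
        collection = new("AnnotationCollection", sets = sets,
                         source = "synthetic signaling collection"),
        pairs = pairs, blocks = blockVec, config = cfg)
}

#' Pairwise Rand index of two labelings
#'
#' Fraction of object pairs on which two labelings agree (both together or
#' both apart); 1 means identical partitions.
#'
#' @param a,b label vectors over the same objects (matched by name when
#'   both are named).
#' @return Rand index in \[0, 1\].
#' @export
randIndex <- function(a, b) {
    if (!is.null(names(a)) && !is.null(names(b))) b <- b[names(a)]
    stopifnot(length(a) == length(b), length(a) >= 2L)
    n <- length(a)
    same_a <- outer(a, a, "==")[upper.tri(diag(n))]
    same_b <- outer(b, b, "==")[upper.tri(diag(n))]
    mean(same_a == same_b)
}

#' Recovery metrics of planted structure
#'
#' Scores pipeline output against the ground truth of a generated
#' dataset: precision and recall of the planted (cancer, TF, pathway)
#' enrichments at \code{pAdj < alphaAdj}, and agreement of detected TF
#' communities with the planted TF blocks (exact-match indicator on the
#' partition induced over the planted-block TFs, plus the pairwise Rand
#' index). Undefined metrics (nothing planted, nothing detected, or no
#' community set supplied) are reported as \code{NA}.
#'
#' @param truth a [SyntheticTruth-class].
#' @param enrichResults output of [enrichTFPathways()] run on the truth's
#'   (filtered) table, or \code{NULL}.
#' @param communitySet a [TFCommunitySet-class] for one cancer of the
#'   truth, or \code{NULL}.
#' @param alphaAdj adjusted-p detection level (default 0.05).
#' @return list with \code{pairRecall}, \code{pairPrecision},
#'   \code{blockExact} (0/1), \code{blockRand}.
#' @export
recoveryReport <- function(truth, enrichResults = NULL,
                           communitySet = NULL, alphaAdj = 0.05) {
    stopifnot(is(truth, "SyntheticTruth"))
    pairRecall <- pairPrecision <- blockExact <- blockRand <- NA_real_
    if (!is.null(enrichResults)) {
        res <- as.data.frame(enrichResults)
        det <- res[res$pAdj < alphaAdj, , drop = FALSE]
        detKey <- paste(det$cancer, det$tf, det$pathway, sep = "\r")
        planted <- truth@pairs
        plantedKey <- paste(planted$cancer, planted$tf, planted$pathway,
                            sep = "\r")
        if (nrow(planted) > 0L)
            pairRecall <- mean(plantedKey %in% detKey)
        if (nrow(planted) > 0L && nrow(det) > 0L)
            pairPrecision <- mean(detKey %in% plantedKey)
    }
    if (!is.null(communitySet) && length(truth@blocks) >= 2L) {
        mem <- communitySet@membership
        tfComm <- stats::setNames(mem$community[mem$type == "TF"],
                                  mem$node[mem$type == "TF"])
        blockTfs <- names(truth@blocks)
        found <- tfComm[blockTfs]
        if (!any(is.na(found))) {
            blockRand <- randIndex(truth@blocks[blockTfs], found)
            blockExact <- as.numeric(blockRand == 1)
        }
    }
    list(pairRecall = pairRecall, pairPrecision = pairPrecision,
         blockExact = blockExact, blockRand = blockRand)
}
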