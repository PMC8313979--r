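# GlycoTFNet

Transcription factors (TFs) shape a cell's glycome by switching the
glycogenes — glycosyltransferases, glycosidases, sulfotransferases and
sugar transporters — on and off, yet the TF→glycogene regulatory map is
mostly unknown. GlycoTFNet is an R package for researchers in systems
glycobiology who want to mine that map from ChIP-Seq/RNA-Seq integration
tables (the Cistrome Cancer export style), in which every candidate
TF→gene edge in a cancer type carries a regulatory potential
`RP ∈ [0, 1]` (binding evidence near the TSS) and a Spearman expression
correlation `ρ ∈ [−1, 1]`.

The pipeline:

1. **Filter** edges to a glycogene universe with inclusive thresholds
   `RP ≥ 0.5`, `ρ ≥ 0.4`, scoring each edge by its binding potential
   `BP = RP·ρ` (kept for network export/layout).
2. **Enrich**: per cancer type, test every (TF, glyco-pathway) pair for
   disproportionate regulation with the one-sided Fisher exact test — the
   hypergeometric upper tail
   `p = Σ_{j≥a} C(K,j)·C(N−K,n−j)/C(N,n)` over the 2×2 table of the TF's
   edges in/out of the pathway versus all retained edges — then control
   the FDR with Benjamini–Hochberg (globally across cancers by default),
   and summarize each cancer–pathway pair by its degree of regulation
   `Σ −log10(p_adj)` over significant TFs.
3. **Communities**: build the bipartite TF–glycogene network, project it
   onto TFs with shared-target-count weights, and partition it with a
   deterministic in-house Clauset–Newman–Moore greedy modularity
   agglomeration (maximal-Q cut of the merge path, specified
   tie-breaking); glycogenes join the community of the plurality of
   their regulators. Networks export to GraphML/SIF for Cytoscape.
4. **Annotate**: test TF groups against signaling gene-set collections
   (local Reactome-style GMT; kept at strict `FDR < 0.1`, set size
   `< 30`) and emit alluvial flow tables linking signaling sets → TFs →
   glyco-pathways.
5. **Simulate**: a synthetic-data generator with planted TF–pathway
   enrichments and planted TF community blocks provides calibrated
   ground truth for power and null studies; `recoveryReport()` scores
   recall/precision of planted pairs and Rand-index agreement of planted
   blocks.

A curated classification of representative glycogenes into 20
glycosylation pathways (dolichol pathway, sialylation, GalNAc-type
O-glycans, heparan sulfate extension, …) ships with the package
(`glycoPathwayFixture()`).

## Worked example

Generate a single-cancer dataset with one planted enrichment (TF007
saturating glycopathway_03 at factor 6) and two planted TF blocks, then
run the full pipeline:

```r
library(GlycoTFNet)

cfg <- syntheticConfig(
    nCancers = 1, nTFs = 40, nGenes = 150, tfActivity = 1,
    pathwaySize = 10,
    plantedPairs  = data.frame(tf = 7, pathway = 3, factor = 6),
    plantedBlocks = list(list(tfs = 11:18, genes = 40:70,  prob = 0.8),
                         list(tfs = 21:28, genes = 80:110, prob = 0.8)),
    seed = 2026)
truth <- generateSynthetic(cfg)
truth
#> SyntheticTruth
#>   TFGeneTable: 489 edges, 39 TFs, 105 genes, 1 cancer type(s)
#>   planted pairs: 1; planted block TFs: 16

filt <- filterRecords(truth@table)   # RP >= 0.5 and rho >= 0.4
filt
#> TFGeneTable: 394 edges, 35 TFs, 92 genes, 1 cancer type(s)

enr <- enrichTFPathways(filt, truth@classification)
res <- as.data.frame(enr)
head(res[order(res$p), c("tf", "pathway", "a", "b", "p", "pAdj")], 3)
#>        tf         pathway  a  b            p         pAdj
#> 63  TF007 glycopathway_03 10  1 1.852610e-09 1.296827e-06
#> 245 TF016 glycopathway_05  5 16 1.787475e-02 1.000000e+00
#> 157 TF011 glycopathway_17  6 16 2.587483e-02 1.000000e+00
```

The planted pair tops the list: TF007 has 11 retained edges, 10 of them
into the 10-gene planted pathway (`a = 10`, `b = 1`), which a background
TF would essentially never do (`p ≈ 2e-9`), and it is the only pair
surviving FDR correction (`pAdj ≈ 1.3e-6`; every unplanted pair adjusts
to ~1). Community detection on the TF projection recovers the planted
blocks exactly:

```r
net  <- buildBipartite(filt)
part <- greedyModularityCommunities(projectTFGraph(net))
cs   <- assignGlycogenes(part, net)
cs
#> TFCommunitySet [CAN_01]: 7 communities, Q = 0.4672

recoveryReport(truth, enr, cs)
#> $pairRecall
#> [1] 1
#> $pairPrecision
#> [1] 1
#> $blockExact
#> [1] 1
#> $blockRand
#> [1] 1
```

`pairRecall`/`pairPrecision` say the FDR-significant set equals the
planted set; `blockExact = 1` and `blockRand = 1` say the detected TF
communities reproduce the two planted blocks exactly. From here,
`overrepresent()` annotates TF groups against a GMT collection,
`buildAlluvialFlows()` emits the signaling→TF→glyco-pathway flow table,
and `exportGraphML()`/`exportSIF()` write Cytoscape-ready networks.

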