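Package: GlycoTFNet
Title: Transcription Factor Regulation of Glycosylation Pathways from
    ChIP-Seq/RNA-Seq Regulatory Tables
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.com>
Description: Infers links between transcription factors (TFs), glycogenes,
    glycosylation pathways and cell-signaling gene sets from tabulated
    ChIP-Seq/RNA-Seq regulatory evidence. Edges carrying a regulatory
    potential (RP) and a Spearman expression correlation (rho) are filtered
    against a glycogene universe, scored by binding potential (RP x rho),
    and tested per cancer type for disproportionate regulation of curated
    glycosylation pathways with one-sided Fisher's exact tests and
    Benjamini-Hochberg correction. Bipartite TF-glycogene networks are
    projected onto TFs by shared-target counts and partitioned with a
    deterministic greedy modularity (CNM) algorithm; communities are
    annotated against signaling gene-set collections and exported for
    Cytoscape. A synthetic-data generator with planted TF-pathway
    enrichments and planted TF community blocks supports calibration and
    power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite
biocViews: NetworkInference, GeneRegulation, GraphAndNetwork, Pathways,
    GeneSetEnrichment
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
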