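Package: mycolink
Title: Multi-Omics Inference of Fungal Signal to Plant-Root Sensor Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links symbiont-synthesized signal metabolites to plant-root
    sensor protein complexes, transcription-factor binding motifs, and
    co-regulated gene clusters. Implements bootstrap RPKM quantification
    from multi-mapped read alignments, coefficient-of-variation filtering
    and K-means co-expression clustering, cumulative-binomial motif and
    annotation enrichment, rank-based co-expression network construction
    refined by annotation-pair likelihood-of-interaction Z-scores,
    transcriptome-derived metabolic turnover prediction, and rule-based
    assembly of the integrated signal-to-phenotype network. A synthetic
    data generator with planted, recoverable ground truth drives testing
    of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    limma,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
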