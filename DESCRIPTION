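Package: aosmeta
Title: Cross-Experiment Meta-Analysis of Antioxidant-System Gene Expression
    Under Abiotic Stress
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable pipeline for meta-analysis of antioxidant-system (AOS)
    gene expression panels across heterogeneous transcriptome experiments
    (microarray intensities and sequencing counts): a three-stage
    normalization cascade (FPKM, housekeeping-gene, control-relative), Ward
    hierarchical clustering of replicate fold-change profiles with principal
    component views, a cluster-based experiment quality filter, and
    cluster-versus-control differential calls with Benjamini-Yekutieli false
    discovery rate control. Also implements efficiency-corrected relative
    quantification for qPCR: window-of-linearity amplification-efficiency and
    Cq estimation from raw fluorescence curves, the multiple-sample
    efficiency-corrected expression ratio, and two-way ANOVA on delta-Cq.
    A synthetic-data generator with planted ground truth (stress signatures,
    batch effects, amplification efficiencies) makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    cluster,
    car,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
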