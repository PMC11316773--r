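Package: blamap
Title: Permutation Tuning Tests and Spatial Cluster Mapping for Amygdala Population Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for genetically defined basolateral-amygdala (BLA)
    neuron populations recorded with single-cell calcium imaging and mapped with
    multiplexed smFISH. Implements distance-to-target tuning analysis of
    deconvolved spike trains (31-bin firing profiles, rotary-shuffle permutation
    test, Benjamini-Hochberg FDR), zone classification of neurons around a food
    or social target, a pooled-resampling population-composition test,
    event-locked contrast response scores for footshock, freezing and social
    interaction with shuffle-based responder classification, AUROC marker-gene
    selection with cluster-profile aggregation, positive-cell calling and
    subregion quantification of smFISH sections, eigen-image PCA of spatial
    expression maps, and Pearson-correlation assignment of smFISH cells to
    single-nucleus transcriptomic clusters. Seeded synthetic-data generators
    (random-walk trajectories, Poisson spike trains with distance tuning or
    event-locked gain, negative-binomial expression counts, 2-D cell layouts
    over eight BLA subregions) provide ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    Matrix,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
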