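Package: epiqtl
Title: Two-Stage Hierarchical Search for Epistatic eQTL in RIL Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-wide search for pairwise epistasis on expression traits in
    recombinant inbred line (RIL) populations. Expression traits are grouped
    into co-expression modules via topological-overlap dissimilarity and a
    top-down branch-cutting procedure, each module is summarised by its first
    principal component ("meta-trait"), and every combination of meta-trait
    and marker pair is tested with an orthogonal two-locus NOIA model adapted
    to homozygous RIL genotypes. A two-step scan (sparse framework markers,
    then dense secondary markers within selected regions) keeps the number of
    tests small, and the false discovery rate over the resulting two-level
    tree of hypotheses is controlled by Benjamini-Hochberg testing within
    families at a calibrated within-family level. A seeded simulator generates
    RIL genotypes on a genetic map and cluster-correlated traits with
    implanted NOIA effects, and estimates power, FDR and per-effect
    heritability over replicate simulations.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
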