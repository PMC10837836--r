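Package: spongefunc
Title: Compositional and Functional Profiling of Sponge Microbiomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for joint compositional and functional analysis of
    sponge-microbiome (holobiont) sequencing data. The compositional arm
    handles ASV count tables: rarefaction, relative abundance, taxonomic
    collapse, abundance filtering, Shannon diversity, log2 Bray-Curtis
    dissimilarities, principal coordinates analysis, PERMANOVA (global and
    pairwise, with exhaustive permutation enumeration on small designs),
    dispersion homogeneity and group-variability contrasts. The functional
    arm quantifies metatranscriptomes at the protein level: transcript
    expected counts are apportioned to ORFs proportionally to peptide
    length, converted to TPM, aggregated to KEGG Orthology (KO) terms, and
    rolled up to KEGG modules with grammar-based completeness evaluation,
    two-level hierarchy summaries, KO multiplicity accounting and
    per-taxon expression splits. Shared-feature intersection analysis and
    filtered permutation-based differential testing connect the two arms.
    A synthetic-data generator with planted group effects, differential
    features and complete or incomplete modules makes every stage testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    vegan,
    edgeR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Microbiome, Metagenomics, Transcriptomics, Normalization,
    Pathways, KEGG, Software
RoxygenNote: 7.3.3
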