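Package: pcflink
Title: Linking Drug Physico-Chemical Features to Pathway Activity and Toxicity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An integrative QSAR/toxicogenomics pipeline that links the
    physico-chemical features (PCFs) of chemicals to pathway-level
    transcriptional activity and to toxicity outcome. Gene expression is
    reduced to per-pathway activity indices by principal component analysis;
    drug perturbation and toxic-versus-nontoxic differential modulation are
    scored with Hotelling T2 statistics on the retained components;
    three-descriptor interaction regressions selected by a genetic algorithm
    link descriptors to pathway components; a Jaccard-overlap pathway map with
    a permutation association test relates descriptor-linked and
    toxicity-linked pathways; and maximum-likelihood discriminant classifiers
    compare descriptor subsets as predictors of toxicity. A synthetic-data
    module generates expression studies, gene-set collections and descriptor
    tables with planted, recorded ground truth so that every stage has a
    recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml,
    ape,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
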