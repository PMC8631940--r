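Package: mgpmap
Title: Process-Centered Multivariate Genotype-Phenotype Mapping for
    Landmark Shape Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates the axis of landmark-based shape variation that
    maximally covaries with founder-allele variation at markers tagging a
    biologically coherent gene set, in multiparental populations such as
    the Diversity Outbred mouse. Provides gene-ontology driven marker
    selection, founder-probability genotype blocks, generalized Procrustes
    superimposition with object-symmetry decomposition and covariate
    residualization, a lasso-regularized partial least squares engine with
    cross-validation, permutation-based variance-explained inference,
    gene-drop sensitivity tests, pairwise process-effect comparison with
    cophenetic stability, mutant effect-direction estimation and
    morphospace projection, and a synthetic multiparental data generator
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
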