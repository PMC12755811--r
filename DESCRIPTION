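Package: hyaflux
Title: Constraint-Based Modeling and Strain Design for Microbial
    Hyaluronic Acid Production
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for constraint-based analysis of small genome-scale
    metabolic models of hyaluronic acid (HA) producing bacteria. Provides
    S4 containers for stoichiometric models with gene-protein-reaction
    (GPR) rules, flux balance analysis (FBA) on a built-in bounded-variable
    simplex, minimization of metabolic adjustment (MOMA) via quadratic
    programming, single- and double-gene deletion screens with synthetic
    lethality classification, an iterative MOMA knockout search for
    product overproduction with a growth-drop pruning rule, alternate-optima
    sampling for up/down-regulation target nomination, biomass and HA
    pseudo-reaction construction from genome and coding sequences, model
    validation screens (growth error, nutrient essentiality, carbon
    sources, confusion-matrix metrics), and deterministic generators for a
    fermentative native-producer / respiring recombinant-producer toy
    model pair.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    quadprog,
    jsonlite,
    xml2,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'hyaflux-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'gpr.R'
    'lp.R'
    'model-core.R'
    'model-io.R'
    'fba.R'
    'moma.R'
    'deletion.R'
    'strain-design.R'
    'biomass.R'
    'validation.R'
    'synthetic-models.R'
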