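Package: RGetaway
Title: R-GETAWAY Autocorrelation Descriptors and Amorphous Solid
    Dispersion Formability Prediction
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes the R-GETAWAY family of 3D molecular
    autocorrelation descriptors from small-molecule structures, with the
    third-order mass-weighted index (R3m) as the headline case. Provides
    molecular structure input/output (SDF, XYZ, multi-model PDB), bond
    perception from covalent radii, molecular influence (leverage)
    matrices, per-atom descriptor decomposition, conformer-ensemble
    descriptor distributions with box-plot summaries, and a logistic
    regression model that maps R3m to the probability of forming an
    amorphous solid dispersion with the copolymer PVPVA, including
    boundary solving, maximum-likelihood refitting, and
    complete-separation handling.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    MASS,
    igraph,
    jsonlite,
    ChemmineR,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Cheminformatics, Software
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'elements.R'
    'structure-io.R'
    'descriptor-core.R'
    'conformer-ensemble.R'
    'dispersibility-model.R'
    'materials-properties.R'
    'synthetic-fixtures.R'
    'reporting.R'
    'RGetaway-package.R'
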