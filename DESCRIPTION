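Package: GroupAdditivity
Title: Extendable Atom-Group Additivity Models for Molecular Descriptors
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Decomposes organic molecules into backbone atom groups (a central
    atom plus its canonically ordered immediate neighbourhood) and predicts
    molecular descriptors by summation of fitted group contributions: heat of
    combustion, heat of formation (indirectly, via combustion stoichiometry),
    octanol/water logP, aqueous solubility logS, molar refractivity, molecular
    polarizability and aqueous toxicity (Tetrahymena pyriformis pIGC50).
    Ships transcribed contribution tables for six descriptors, refits new
    tables from training data by Gauss-Seidel least squares, and validates
    them with a deterministic shifted k-fold cross-validation scheme.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, ChemmineR, ChemmineOB, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'GroupAdditivity-package.R'
    'chem-utils.R'
    'molecule.R'
    'atomtype.R'
    'fragment.R'
    'specials.R'
    'eligibility.R'
    'params.R'
    'fitting.R'
    'crossval.R'
    'predict.R'
    'synthdata.R'
    'config.R'
    'cli.R'
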