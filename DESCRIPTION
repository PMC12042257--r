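Package: chemspan
Title: Span-Corruption Objectives and Covalent-Adduct Encoding for
    Unified Protein/SMILES Sequence Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for building and evaluating unified protein/chemical
    sequence models that treat amino-acid strings and SMILES as one
    language. Implements a fixed 203-token dual-domain vocabulary with
    reversible character-level tokenization, T5-style span corruption for
    SMILES denoising and the protein-to-SMILES masking objective in which
    masked residue spans are decoded as chemistry, deterministic
    amino-acid/peptide/adduct SMILES construction including covalent
    adduct grafting by direct molecular-graph editing, dataset assembly
    for sequence-level covalent-binder tasks (leakage-free pair splits,
    balanced negative mixing), an evaluation suite (protein-centric
    F-max, AUPRC, concordance index, RMSE and the r_m^2 family, adduct
    and position accuracies), synthetic fixture generators, and a
    smoke-scale encoder-decoder training harness with an audited
    closed-form parameter count.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    ChemmineOB,
    ChemmineR,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
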