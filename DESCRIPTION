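Package: paleoproteo
Title: Palaeoproteomic Authentication and Phylogenetics of Ancient Bone Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for authenticating and analysing ancient bone and dentine
    proteomes: diagenetic prescreening indices from ATR-FTIR spectra (infrared
    splitting factor, amide-to-phosphate ratio) and elemental C:N ratios; ZooMS
    peptide-mass-fingerprint processing with isotope-envelope estimation of the
    glutamine deamidation alpha-value; intensity-based quantification of
    glutamine/asparagine deamidation per protein with two-component mixture
    classification of endogenous versus contaminating proteins; rule-based
    consensus protein sequence calling with substitution authentication and
    concatenated-alignment assembly; and maximum-parsimony phylogenetics (Fitch
    scoring, exact branch-and-bound search, nonparametric bootstrap, majority-rule
    consensus). A synthetic-data module generates FTIR spectra, MALDI isotope
    envelopes, peptide-spectrum-match tables and simulated alignments with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    mclust,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
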