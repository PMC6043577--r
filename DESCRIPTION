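Package: cpmgdyn
Title: Two-State Conformational Exchange Analysis of CPMG Relaxation
    Dispersion Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of protein micro-to-millisecond conformational
    dynamics from NMR relaxation data. Converts CPMG peak intensities to
    effective transverse relaxation rates, fits a global two-state
    (Bloch-McConnell) exchange model across residues, magnetic fields and
    temperatures, and extracts excited-state and transition-state
    thermodynamics by Van't Hoff and Eyring analysis. Also provides
    backbone R1/R2/heteronuclear-NOE relaxation fitting with rotational
    correlation time estimation, amide temperature-coefficient
    classification, chemical-shift-perturbation and single-site binding
    (KD) titration fitting, and internal-cavity volume calculation on
    protein structures by a two-probe rolling-probe grid method. A
    synthetic-data generator with known ground truth makes every stage
    verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    bio3d,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
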