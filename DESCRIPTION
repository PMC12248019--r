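Package: nascore
Title: Assessment of Nucleic Acid Structure Predictions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores predicted RNA, DNA and nucleic-acid complex structures
    against experimental references with biomolecule-agnostic metrics
    (TM-score, GDT_TS, clash-penalised lDDT and a sequence-independent
    structural alignment score), base-pair topology recovery (pseudoknots,
    singlets, non-canonical and intermolecular pairs) scored by F1
    conventions, contact-based interface metrics (ICS, IPS, i-lDDT),
    ligand-pocket metrics, stoichiometry and Cn/Dn point-group symmetry
    assessment, multiple-sequence-alignment effective depth (Neff), and an
    outlier-trimmed weighted Z-score ranking with bootstrap confidence
    intervals and template-difficulty covariates. A deterministic
    synthetic-structure generator builds coarse-grained nucleic acids,
    symmetric assemblies, graded-quality perturbed predictions, MSAs and
    submission rosters so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    stats,
    utils,
    withr,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
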