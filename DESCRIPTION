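Package: dscardio
Title: Cardiac Electrophysiology and Gene-Dosage Phenotyping for Segmental Trisomy Mouse Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative phenotyping pipeline for Down-syndrome mouse models
    (Ts65Dn, Ms5Yah and their compound): multi-lead mouse ECG simulation and
    delineation (wave amplitudes, PR/QT/QTc intervals, heart rate, frontal
    electrical axis), qualitative QRS-morphology scoring (fragmented QRS,
    slurring, S-wave absence) with cohort contingency statistics (exact Fisher
    tests with explicit tail conventions, transmission-ratio chi-square under
    Mendelian or line-adjusted expectations), and aneuploidy gene-dosage
    expression analysis (expression filtering, fold-change computation,
    seven-way genotype-pattern dosage grouping, trisomic-segment summaries,
    ANOVA screening and hierarchical clustering). A synthetic-data module
    generates every input so the full pipeline is reproducible without
    animal recordings or array downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    ape,
    signal,
    SummarizedExperiment,
    S4Vectors
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
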