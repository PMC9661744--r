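Package: ctdyn
Title: Paired CSF and Plasma ctDNA Dynamics: Concordance, Clonality and
    Molecular Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for paired cerebrospinal-fluid (CSF) and
    plasma circulating tumor DNA (ctDNA) studies. Reads somatic variant
    calls (VCF) with allele-frequency and read-support annotations,
    applies panel-style filtering rules, and derives per-sample ctDNA
    metrics (maxVAF, mean VAF, concentration in haploid genome
    equivalents per mL). Quantifies cross-compartment agreement with an
    asymmetric consistency statistic, Venn partitions and per-gene
    Cohen's kappa; assigns baseline clonal/subclonal status by the
    relative 25-percent-of-maxVAF rule and tracks clonal evolution
    across timepoints; classifies molecular response from longitudinal
    ctDNA concentration and compares response groups with Kaplan-Meier,
    log-rank and univariate proportional-hazards analyses. A seeded
    synthetic-cohort generator emulates compartment-asymmetric
    detection, treatment-driven concentration changes and
    group-dependent survival so the whole pipeline is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    survival,
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
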