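Package: panelscope
Title: Hotspot qPCR Panel Coverage Analysis for NGS-Identified Somatic Mutations
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies how many somatic mutations identified by clinical
    next-generation sequencing would be detectable on a predefined hotspot
    qPCR panel (such as the Idylla BRAF/EGFR/KRAS/NRAS cartridges).
    Normalizes cDNA and protein HGVS-style variant names across long
    (three-letter) and short (one-letter) spellings, matches cohort records
    against a panel-definition file, deduplicates to unique study-sample
    cases, and produces gene-level, tier-stratified, diagnosis-level and
    sample-level coverage summaries together with an extra-mutation
    (co-mutation) analysis. Includes a configurable clinical triage rule
    engine for first-line versus reflex molecular testing decisions, and a
    seeded synthetic-cohort generator with truth labels for end-to-end
    validation without access to protected patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
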