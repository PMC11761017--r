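Package: escapeclock
Title: Timing Immune-Escape Mutations in Tumor Evolution
Version: 0.1.0
Authors@R: person("escapeclock", "maintainers", email = "escapeclock@example.org", role = c("aut", "cre"))
Description: Posterior timing of somatic SNVs relative to copy-number gains
    and whole-genome doubling (WGD), timing of HLA loss of heterozygosity
    relative to WGD, per-patient early/late classification of pathway
    mutations against a driver-gene background clock, and cancer-type-level
    timeline aggregation. Includes a synthetic cohort generator with known
    ground-truth mutation times for end-to-end validation, mutation-class
    filtering and pathway prevalence utilities, and a deterministic pipeline
    driver with a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
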