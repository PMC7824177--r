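Package: metaboldt
Title: Holistic Metabolomic Laboratory-Developed Test Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable pipeline for a holistic metabolomic laboratory-developed
    test (LDT) on direct-infusion mass spectrometry peak tables. Provides
    cross-spectrum m/z alignment, total-signal normalization, prevalence and
    mass-range filtering, putative metabolite annotation disambiguated by
    biochemical context (intensity-correlation plus pathway adjacency),
    Monte-Carlo permutation scoring of metabolite set overrepresentation for
    four set categories (disease-associated, pathway-associated,
    abnormal-concentration, and location-based), per-individual abnormality
    profiling via leave-one-out Z-scores, diagnostic scores with ROC-based
    performance estimation, a seeded synthetic-cohort generator with known
    ground truth, and metabolite set name-cloud rendering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
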