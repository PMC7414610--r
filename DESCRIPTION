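Package: cprnfl
Title: Circumpapillary RNFL Thickness Profiling and Reliability Analysis for
    Hand-Held OCT
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Measures circumpapillary retinal nerve fiber layer (cpRNFL)
    thickness from segmented hand-held OCT raster volumes by polar resampling
    on circular rings and annuli expressed in visual-angle degrees, partitions
    the profile into GDx-style quadrants, applies scan- and pair-level
    inclusion rules, and evaluates repeatability (test-retest) and
    reproducibility (inter-assessor) with intraclass correlation coefficients,
    within-subject coefficients of variation, bias tests and Bland-Altman
    limits of agreement. Includes feasibility bookkeeping for acquisition
    success rates and a synthetic retinal phantom generator with controllable
    variance components so the whole pipeline can be exercised without
    patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
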