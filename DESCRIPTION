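Package: natparadox
Title: Conservation-Paradox Analysis of Naturalized yet Threatened Plants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to identify and analyse plant species that are naturalized
    outside their native range while threatened inside parts of it (the
    "conservation paradox"). Provides taxonomic name harmonization against a
    checklist with synonym resolution and hybrid/apomict exclusion,
    standardization of heterogeneous national Red List categories to IUCN
    codes, classification of species along a net-loss / paradox / net-increase
    continuum, gridded area-of-occupancy (AOO) estimation from point
    occurrence records partitioned by threat status, model II (major axis)
    regression and paired nonparametric comparisons of naturalized versus
    threatened AOO, family-level phylogenetic dispersion tests, and a
    deterministic synthetic-world generator emulating the structure of
    checklist, naturalization, Red List and occurrence databases so the whole
    pipeline can be exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
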