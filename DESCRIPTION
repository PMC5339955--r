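Package: endodiv
Title: Tissue-Wise Endophyte Community Diversity and Bioactivity Screening
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for culture-based fungal endophyte surveys and
    downstream bioactivity screens. Builds taxon-by-tissue abundance matrices
    from isolate tables, computes the classical per-assemblage (alpha) diversity
    suite (Shannon, Simpson, Brillouin, Menhinick, Margalef, equitability,
    Berger-Parker, Chao-1, Fisher's log-series alpha), presence-absence
    similarity (Jaccard, Sorensen) and multi-sample beta-diversity indices
    (Whittaker, Cody, Wilson-Shmida, Routledge, Mourelle, Harrison, Williams).
    For bioactivity screening it provides MTT percent-growth-inhibition
    arithmetic, four-parameter-logistic IC50 estimation with censoring,
    disc-diffusion zone-of-inhibition summaries and broth-dilution MIC/MBC
    logic, plus a synthetic-data module that emulates the sampling structure of
    each assay so that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
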