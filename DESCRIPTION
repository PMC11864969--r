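Package: phosfor
Title: Phosphate Storage Budgets for Benthic Foraminifera
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies intracellular phosphate storage in benthic
    foraminifera and scales it to regional seafloor budgets. Estimates
    specimen biovolumes from 2D microscope measurements using geometric
    shape assignments with hidden-height rules, converts autoanalyser
    phosphate measurements of freeze-thaw extracts into per-individual
    contents and intracellular concentrations, computes
    assemblage-based phosphate stocks with genus-mean imputation,
    riverine-runoff buffer budgets and areal extrapolations, and
    processes energy-dispersive X-ray spectroscopy (EDS) elemental maps
    via per-pixel intensity-to-noise ratio transforms, median
    filtering, 16-colour rendering and similarity-transform
    registration. Includes seeded synthetic-data generators (specimen
    tables, extraction sets, assemblages, Poisson-count EDS phantoms)
    with stored ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stats,
    ggplot2,
    readr,
    jsonlite,
    tiff,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
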