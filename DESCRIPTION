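Package: mzident
Title: Mass-Based Metabolite Identification Across Multiple Record Sources
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Offline mass-based metabolite identification for untargeted
    LC-MS metabolomics. Takes a plain list of m/z values or a CAMERA-style
    annotated peak table, computes neutral monoisotopic masses under adduct,
    isotope and charge annotations, searches one or more tabular metabolite
    record sources within a ppm tolerance, fills missing chemical
    identifiers (KEGG, PubChem CID/SID, HMDB, InChI/InChIKey) by
    cross-referencing, and merges hits from all sources into a
    non-redundant identification table keyed on the first 14 characters of
    the InChIKey, so stereoisomers collapse while structural isomers stay
    apart. Includes seeded synthetic-data generators with ground truth for
    every stage, a tabular report writer, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    patchwork,
    readxl,
    testthat (>= 3.0.0),
    writexl
Config/testthat/edition: 3
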