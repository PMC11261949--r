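Package: hrdsix
Title: Homologous Recombination Deficiency Classification from Six
    Mutational-Context Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies breast and ovarian tumours as homologous
    recombination deficient (HRD) or proficient (HRP) from somatic
    substitutions, small insertions/deletions, and allele-specific copy
    number segments.  Implements the SBS-96, ID-83 and CN-48
    mutational-context classification schemas, a Fisher-exact channel
    enrichment screen with Benjamini-Hochberg correction, aggregation of
    enriched channels into six genomic features, a cross-validated linear
    support vector machine with Platt-style probability calibration,
    down-sampling of whole-genome catalogues to whole-exome resolution,
    and a seeded synthetic cohort generator so the entire pipeline can be
    exercised without access to controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
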