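Package: immunomark
Title: Immunogenetic Marker Identification from Amplicon and Whole-Transcriptome Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Annotates immunoglobulin and T-cell receptor (IG/TR) gene
    rearrangements from sequencing reads into 22 junction classes across the
    seven IG/TR loci, identifies candidate minimal residual disease (MRD)
    markers under abundance and cross-case uniqueness filters, and quantifies
    how well RNA-seq-derived rearrangements recover DNA-amplicon-derived
    markers. Ships a synthetic clone and read simulator (clonal plus
    polyclonal rearrangements, per-tube amplicon reads, paired-end
    transcriptome fragments under a three-tier transcription model) so the
    full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    stringi,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
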