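Package: locovar
Title: Local Covariation Profiling for Detecting Shift Errors in Protein
    Alignments
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects systematic misalignments (shift errors) in protein
    multiple sequence alignments using local covariation.  Pairwise
    mutual information between alignment columns is corrected with the
    average-product correction (MIp) and z-normalized (Zp); the mean Zp
    over a sliding window of columns gives a local-covariation profile
    whose peaks flag candidate misaligned regions.  Includes a
    planted-shift synthetic alignment generator with ground-truth
    labels, curation helpers (percent-identity neighbour joining,
    segment shift edits, profile recomputation), batch screening of
    alignment collections, and optional inter-residue distance
    annotation from PDB structures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
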