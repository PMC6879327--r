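Package: quadchip
Title: G-Quadruplex Motif and Telomeric Repeat Analytics for ChIP-Seq Peaks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the association between potential
    G-quadruplex (PG4) motifs and protein binding sites mapped by
    ChIP-Seq, motivated by extra-telomeric binding of the shelterin
    protein TRF2. Scans DNA for PG4 motifs under configurable
    G-run/loop parameters, detects telomeric TTAGGG repeats and
    classifies telomeric reads, intersects replicate peak sets,
    annotates peaks by TSS proximity and gene features, partitions
    reads into sub-telomeric and interstitial compartments, computes
    FRiP and bin-level ChIP-vs-input enrichment, tests PG4 enrichment
    in peaks against length-matched random-region controls with
    Fisher's exact test, and analyses G4 fluorescent intercalator
    displacement (G4-FID) titrations including DC50 and an indicative
    Hill fit. A synthetic-data generator with known ground truth
    exercises every step.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
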