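Package: phenoplate
Title: Multi-Trait High-Throughput Screening of Seed Germination and
    Rosette Growth in Multi-Well Plates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image- and absorbance-based phenotyping of plate assays for
    characterizing seed-priming biostimulants. Counts seeds in scanned
    96-well plates by thresholding, connected components and solidity-based
    cluster splitting; normalizes dual-wavelength (570/690 nm) tetrazolium
    (MTT) plate-reader absorbance to per-seed germination activity; tracks
    rosette green area in time-lapse images of 48-well plates and estimates
    relative growth rates; computes the RGB vegetation indices NGRDI, GLI
    and VARI over plant masks; and combines the traits into the Plant
    Biostimulant Characterization (PBC) index with a mode-of-action
    classification. A synthetic-data generator emulates all three data
    streams with exact ground truth so the full pipeline can be validated
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    png,
    tiff,
    EBImage,
    emmeans,
    stats,
    grDevices,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
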