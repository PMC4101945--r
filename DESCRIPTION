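Package: rheosense
Title: Multilevel Remote-Sensing Resource Assessment for Scattered Wild Plants
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the standing stock of a scattered wild plant
    population (such as wild rhubarb on alpine pasture) by combining three
    observation levels: satellite NDVI vegetation masking at 30 m pixels,
    object-based detection of individual plant canopies in 0.1 m aerial
    imagery (multiresolution region-merging segmentation, fuzzy object
    classification, minimum-mapping-unit filtering), and fenced quadrat
    ground surveys.  The headline estimate is amount = vegetation area x
    plant density; the ratio of the aerially detectable ("effective") stock
    to the all-sizes ground-survey ("future") stock gives a sustainable
    harvest quota.  A synthetic-scene generator with known ground truth
    supports parameter-recovery validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
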