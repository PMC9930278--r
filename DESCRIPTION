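Package: colonyscan
Title: Colony Detection and Petite Frequency Estimation from Petri Dish Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and classifies Grande and Petite yeast colonies in scanned
    petri-dish images and turns the counts into per-plate Petite frequencies
    with a binomial sampling-error model. Provides a classical detector built
    on circular Hough plate localization, multi-level Otsu thresholding,
    watershed splitting of touching colonies and unsupervised size/intensity
    clustering; a sliced-inference framework with greedy non-maximal merging
    for pluggable detection backends; COCO-style evaluation (precision,
    recall, average precision, mAP); and a seeded synthetic plate-image
    generator with exact ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    yaml,
    optparse,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
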