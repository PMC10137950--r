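Package: hipoffset
Title: Three-Dimensional Hip Offset Morphometry and Virtual Cup Implantation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures femoral, acetabular, cup and global offsets of the hip
    from triangulated bone surface models, in three dimensions and on a
    simulated anteroposterior radiograph. Provides least-squares sphere
    fitting of the femoral head, total-least-squares femoral shaft axis
    extraction, anterior-pelvic-plane coordinate frames, virtual acetabular
    cup implantation flush to the true acetabular floor, femur-to-pelvis
    matching at the native hip rotation center, and cohort-level statistics
    (Student's t, Pearson correlation, intraclass correlation). A parametric
    synthetic femur/hemipelvis generator with full ground truth makes every
    measurement stage verifiable by parameter recovery without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
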