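Package: swnc
Title: Sensor-Weighted Network Classification for Multi-Sensor Activity Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the robustness of body-worn accelerometer
    activity recognition under sensor disturbances. Implements a two-level,
    accuracy-weighted decision-fusion ensemble (the sensor-weighted network
    classifier) over one-vs-rest base classifiers, Euler-angle rotational and
    additive white Gaussian sensor-noise models, sliding-window feature
    extraction with ROC-based feature ranking, a synthetic multi-sensor biaxial
    accelerometer data generator, and a repeated-trial evaluation protocol that
    compares single-sensor recognition against fusion across increasing
    disturbance levels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    class,
    ggplot2,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
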