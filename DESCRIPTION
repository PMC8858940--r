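Package: tabataEE
Title: Energy-Expenditure Modelling for Tabata Training from Accelerometer and Heart-Rate Streams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools to estimate per-window energy expenditure (kcal per 10 s)
    during classic Tabata high-intensity interval training from tri-axial
    accelerometer counts and heart rate. Provides a synthetic cohort
    generator emulating the sensor streams, vector-magnitude window
    features, Pearson-correlation variable screening, p-value stepwise
    linear regression, a from-scratch single-hidden-layer backpropagation
    network with momentum and adaptive learning rate, and an agreement
    validation battery (Bland-Altman limits, MAPE, RMSE, per-stage errors)
    with tidy outputs and ggplot2 figures.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    readr,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
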