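Package: fluxtransfer
Title: Transferring Station-Trained Carbon-Water Flux Models by Climate Similarity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A framework for upscaling daily net ecosystem exchange (NEE) and
    water flux (WF) from eddy-covariance flux stations to meteorological
    stations. Random-forest flux models are trained per station category under
    grouped (leave-stations-out) repeated k-fold cross-validation; the
    transferability of each model to a new station is predicted from
    per-factor Euclidean distances between day-of-year climatologies of the
    station and the model's training set, via a multiple linear regression of
    test-station R2 on those distances. Models predicted to reach R2 >= 0.5
    are screened and used to simulate daily station fluxes. Includes a
    synthetic station-network generator with covariate-driven flux truth for
    testing the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    generics,
    ggplot2,
    ranger,
    zoo,
    readr,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    optparse,
    withr
Config/testthat/edition: 3
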