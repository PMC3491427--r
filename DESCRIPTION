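Package: opnet
Title: Time-Evolving Functional Networks from Order Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates time-evolving functional connectivity between the
    channels of a multivariate time series by encoding each channel into a
    sequence of order (rank) patterns and declaring two channels linked at a
    time point when their patterns are identical. Yields a temporal sequence
    of binary networks together with time-resolved graph measures (link
    density, clustering, connected components, graph distances) and a sliding
    paired permutation test for comparing conditions. Includes estimators for
    the embedding dimension (false nearest neighbours) and delay
    (auto-mutual-information first minimum), a coupled-Lorenz benchmark of
    link-detection accuracy against windowed correlation, and seeded
    synthetic multichannel generators so the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
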