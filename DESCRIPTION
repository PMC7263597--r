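Package: horstein
Title: Posterior-Matching Feedback Decoding for Noisy Binary Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for turning unreliable two-state inputs (switches, motor-imagery
    brain-computer interface classifiers, eyebrow switches) into arbitrarily
    reliable 1-of-n selection using posterior-matching (Horstein) feedback
    coding. Provides capacity bounds for symmetric and asymmetric binary
    channels, a Bayesian bisection decoder over piecewise-linear posteriors
    with block termination, trisection and q-ary variants, non-uniform priors,
    reliability-weighted updates and information-metered undo; backspace
    reference coding and its closed-form Gamma approximation; Gilbert-Elliott
    bursty channel models; online adaptation of channel statistics; 2D
    selection geometry (entropy-scheduled multi-axis decoding, diagonal splits,
    highest-density-interval viewports, nonlinear display warps); and a Monte
    Carlo harness for evaluating hypothetical interface designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
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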