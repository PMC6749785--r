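Package: wigglecamo
Title: Simulated Wiggle-Discrimination Psychophysics with Disruptive
    Camouflage Stimuli
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates disruptive-camouflage stimuli (band-pass noise
    textures posterised to two tones, optional edge enhancement, leafy
    backgrounds with per-leaf shadows, and snake-shaped targets with a
    parametric wiggle amplitude), runs simulated two-alternative
    forced-choice staircase experiments against statistical observers,
    fits logistic psychometric functions to recover wiggle-discrimination
    thresholds, and performs default-prior (JZS) Bayes-factor t tests
    with bootstrap group summaries. All user-facing functions take and
    return tidy data frames so full studies compose with the pipe.
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
    ggplot2,
    generics,
    farver,
    EBImage,
    png,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
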