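Package: pupilagree
Title: Automated Pupillometry Reading and Bland-Altman Reproducibility
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for reading pupillary light reflex recordings from
    binocular pupillometers and assessing the reproducibility of minimal
    pupil size measurements. Implements a robust automated reading
    algorithm (Hampel/MAD outlier removal, validity and step filtering,
    quality-weighted percentile estimation over a fixed post-onset
    window), an emulated human-assisted whole-stimulus-minimum reading,
    Bland-Altman agreement statistics with exact t-based confidence
    intervals for bias and limits of agreement, proportional-bias testing
    with a ratio-scale fallback, and a synthetic pupillary light reflex
    generator (phasic constriction, pupillary escape, latent
    constrictions, blink artifacts) for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
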