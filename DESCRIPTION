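Package: hoofbeat
Title: Upper-Body and Limb Kinematics for Equine Gait Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stride-level analysis of equine gait from per-limb hoof events
    and vertical motion of the head, withers and pelvis, covering walk, trot,
    toelt and pace. Provides a synthetic gait generator with footfall timing,
    dissociation and vertical range-of-motion structure matching published
    reference kinematics for Warmblood, Iberian and Icelandic horses; a
    surrogate hoof-event detector; double integration of vertical
    acceleration to displacement with per-stride drift correction; stride
    segmentation and time normalization; per-stride temporal variables (duty
    factor, diagonal and lateral dissociation, suspension), vertical range of
    motion, extremum timing as percent of limb stance, and movement-symmetry
    indices (HDmin, HDmax, PDmin, PDmax) with the standard lameness-screening
    inclusion filter; between-segment phase differences; and mixed-model
    group summaries with estimated marginal means and Tukey-adjusted
    contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    jsonlite,
    lme4,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    ggplot2,
    lmerTest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
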