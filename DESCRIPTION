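Package: oxyclock
Title: Circadian Period Estimation for Photosynthetic Oxygen Rhythms and
    qPCR Relative Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for free-running circadian rhythms of
    photosynthetic oxygen evolution measured with optical oxygen sensors
    (optodes) in dinoflagellate cultures and symbiotic corals. Provides a
    synthetic-data generator emulating light:dark entrainment followed by
    constant-light free run with amplitude damping, instrument drift and
    replicate period jitter; blank/drift correction, detrending and
    light-phase segmentation; a zero-padded, Hann-windowed Fourier
    periodogram with quadratic sub-bin peak interpolation for dominant
    circadian period extraction, plus an independent least-squares cosinor
    period scan; qPCR relative expression by the delta-delta-Ct method with
    amplification-efficiency correction and reference-gene stability
    ranking; and the comparison statistics used in chronobiology studies
    (paired t-tests, one-way ANOVA, Tukey HSD with compact letter display).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
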