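Package: cpetoues
Title: Oxygen Uptake Efficiency Slope and Ventilatory Threshold Analysis for
    Cardiopulmonary Exercise Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reducing breath-by-breath cardiopulmonary exercise test
    (CPET) data and for studying the oxygen uptake efficiency slope (OUES).
    Breath series are smoothed with a moving average, averaged into 10-second
    bins and labelled with ramp-protocol phases. Ventilatory landmarks (aerobic
    threshold via the VE/VO2 ventilatory-equivalent nadir with a V-slope
    secondary criterion, anaerobic threshold via the VE/VCO2 nadir with a
    VE-versus-VCO2 breakpoint secondary, the RER = 1.0 crossing, and peak VO2)
    are located automatically. The OUES (slope a of VO2 = a*log10(VE) + b) is
    fitted over submaximal and peak windows and normalised by body mass, fat
    free mass and Haycock body surface area. A method-comparison battery
    (ordinary least products regression, typical percentage error, ICC(3,1),
    Bland-Altman percentage limits of agreement, paired t-tests and
    repeated-measures ANOVA with Bonferroni post hocs) quantifies agreement
    between submaximal and peak OUES. A synthetic-data module generates ramp
    CPET breath series and cohorts with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    ggplot2
Config/testthat/edition: 3
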