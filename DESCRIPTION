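Package: biocyloop
Title: Biocybernetic Adaptation and Psychophysiological Feature Pipelines
    for Simulated Shooting-Range Training
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for characterising trainee physiology and closing a
    biocybernetic loop around a simulated shooting-range task.  Provides
    an integral pulse frequency modulation (IPFM) generator for
    RR-interval series and a band-structured frontal EEG generator, the
    corresponding feature pipelines (SDNN, RMSSD, Welch band powers;
    absolute log bandpowers, engagement index, frontal alpha asymmetry,
    theta/beta ratio), a nonparametric repeated-measures statistical
    battery (Lilliefors-type normality screen, Friedman omnibus,
    Wilcoxon signed-rank post-hocs with Bonferroni adjustment),
    Simulator Sickness Questionnaire scoring with cut-off flags, and a
    zone-controller adaptation engine that modulates simulation
    difficulty to drive heart rate into a trainer-specified target zone.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
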