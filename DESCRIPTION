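Package: netrate
Title: Single-Terminal Norepinephrine Transporter Uptake Kinetics from
    Fluorescence Time-Lapse Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies norepinephrine transporter (NET) reuptake rate at
    single sympathetic nerve terminals from confocal z-stack time series of a
    fluorescent transporter substrate. Implements delta-F/F normalisation
    against a pre-label baseline, ordinary least-squares slope estimation over
    the linear uptake phase, washout-decline analysis, percent-excess and
    fold-change statistics with root-sum-of-squares error propagation, and the
    accompanying nonparametric group-comparison pipeline (Lilliefors
    normality screen, Student/Welch/Mann-Whitney selection, Kruskal-Wallis or
    Friedman omnibus with Dunn's post-hoc tests). A synthetic confocal
    time-lapse generator renders varicose terminals ("beads on a string")
    with known uptake, washout, photobleaching and Q10 temperature kinetics,
    providing ground truth so every stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    graphics,
    grDevices,
    jsonlite,
    nortest,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
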