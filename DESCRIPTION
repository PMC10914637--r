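Package: socialcue
Title: Simulation and Inference for Reliability-Weighted Social Cue Use
Version: 0.2.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying how decision makers weight a social cue
    (another individual's gaze direction) against non-social object value
    information according to cue reliability, in the style of macaque
    event-related fMRI experiments. Provides generators for gaze-versus-object
    choice task schedules with asymmetric cue reliabilities and for
    repetition-suppression face designs; stochastic choice agents with
    configurable cue weights, lapse rates and site-specific perturbations
    emulating transcranial ultrasound stimulation; mixed-effects behavioral
    models with Satterthwaite tests, Kolmogorov-Smirnov diagnostics and a
    fixed-effects fallback; gamma hemodynamic-response convolution and
    event-related design-matrix construction; region-of-interest BOLD
    simulation with known injected effects; high-pass filtering and
    least-squares model fitting with session-level random-effects contrasts;
    and a trial-epoch time-course pipeline with per-timepoint regression,
    psychophysiological interaction terms, permutation inference,
    false-discovery-rate correction across timepoints and Holm-Bonferroni
    correction across regions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
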