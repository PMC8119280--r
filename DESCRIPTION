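Package: stairbold
Title: Adaptive Staircase Detection Sessions and Event-Related BOLD
    Simulation and Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis tools for near-threshold visual
    detection experiments run in the scanner.  Simulates yes/no observers
    with parametric psychometric functions, generates 60-trial sessions of
    two randomly interleaved 1-up/1-down descending staircases with catch
    trials and an event-related timeline, classifies trials with the
    five-consecutive-trial zero-slope regression rule (ST/UT/SNT/UNT/OT)
    and estimates the 50% visual detection threshold as the mean duration
    of at-threshold trials.  Provides the accompanying group statistics
    (pooled two-sample Student t tests on raw values or printed summaries,
    Pearson correlations, catch-trial error summaries), a synthetic 4-D
    BOLD generator with HRF-convolved condition regressors, drift and
    AR(1) noise, the matching preprocessing steps (dummy-scan discard,
    high-pass filtering, Gaussian smoothing), voxelwise GLM fitting,
    random-effects group maps, a two-factor mixed-design ANOVA with
    post-hoc between-group maps, Monte-Carlo cluster-extent thresholding,
    and ROI-level group comparisons, plus a reproducible end-to-end
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
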