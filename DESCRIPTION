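Package: rvcerp
Title: Trial-to-Trial ERP Variability Analysis via Response Variance Curves
Version: 0.1.0
Authors@R:
    person("rvcerp", "maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying intra-individual (trial-to-trial) variability
    of event-related potentials recorded from a two-channel prefrontal EEG
    montage (Fp1/Fp2) during an auditory oddball task. Implements epoch
    preprocessing (segmentation, baseline correction, amplitude-threshold
    artifact rejection, moving-average smoothing), the response variance curve
    (RVC) and its window measures (peak amplitude variability AMPV, peak
    latency variability LATV, 50% fractional-area latency variability FALV,
    and area-under-curve variability AUCV) for the P200 and P300 windows,
    normalized hemispheric asymmetry indices, and the statistical layer used
    to relate these measures to mild cognitive impairment status: two-sample
    t-tests (Student/Welch), Pearson chi-squared tests, and nested logistic
    regression models with demographic and MMSE covariates. A fully seeded
    synthetic-data module simulates oddball epoch cohorts with controlled
    amplitude/latency jitter, noise, artifacts, and group effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
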