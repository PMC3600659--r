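Package: prlterp
Title: Probabilistic Reversal Learning Simulation and Feedback-Locked ERP
    Analysis
Version: 0.1.0
Authors@R:
    person("PRLT", "Maintainers", email = "maintainers@prlterp.org",
           role = c("aut", "cre"))
Description: Tools for simulating and analysing feedback-driven decision
    making in addiction research. Implements a probabilistic reversal
    learning task (PRLT) engine with exact-count false-feedback
    scheduling, reinforcement-learning agent cohorts with exposure
    covariates (gambling intensity, cocaine-use severity), behavioural
    dependent measures (reversal cost, asymptotic learning, decision
    latencies, rank-based partial correlations), synthetic feedback-locked
    EEG epoch and cortical current-density generators, feedback-related
    negativity (FRN) and P3 component scoring with amplitude-based
    artifact rejection, voxelwise current-density-FRN correlation mapping
    with an area-level voxel-count rule and cross-group correlation
    contrasts, and repeated-measures mixed ANOVA/ANCOVA with
    Greenhouse-Geisser correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
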