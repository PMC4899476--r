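Package: insulaMVPA
Title: Multivoxel Pattern Decoding of Vitality Form Versus Velocity
    Processing in Simulated Insular BOLD Data
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates event-related fMRI cohorts with task-tuned voxel
    populations in insular regions of interest and re-implements, end to
    end, a multivoxel pattern analysis that discriminates vitality-form
    processing from velocity processing of observed actions:
    single-trial beta-series estimation in a fixed peristimulus window,
    linear support-vector-machine decoding with an alternate-run
    cross-validation scheme and a permutation chance level, exact
    one-sided Wilcoxon signed-rank group inference, and group
    discriminative overlap maps with Monte Carlo / exact binomial nulls
    and Benjamini-Hochberg FDR thresholding. A companion kinematics
    module generates minimum-jerk reaching velocity profiles, compares
    stimuli by dynamic time warping, and simulates and fits logarithmic
    vitality/velocity judgments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    RNifti,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
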