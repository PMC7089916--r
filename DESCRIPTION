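Package: scansoc
Title: Predictability of Association Patterns from Scan-Sampled Subgroup Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of association patterns in group-living animals from
    focal-follow scan samples of subgroup composition. Implements constrained
    permutation null models that preserve subgroup size, focal identity,
    individual gregariousness and temporal autocorrelation; Shannon entropy of
    subgroup composition with permutation-based expectations (entropy ratio,
    Kullback-Leibler divergence, Jensen-Shannon distance); dyadic association
    statistics (simple ratio index, pairwise affinity value, permutation
    significance, bootstrap precision); Elo dominance ratings from supplant
    interactions; and assortativity analysis via all-subsets AICc multimodel
    inference with dyad-flip resampling. Includes a synthetic scan-data
    generator with injectable dyadic affinity structure for calibration and
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    lme4
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
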