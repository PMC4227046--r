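Package: mnphys
Title: Intrinsic Excitability and Dendritic Morphometry of Neonatal Spinal Motoneurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Protocol-driven analysis of current-clamp recordings from neonatal
    spinal motoneurons: rheobase step-search, dV/dt spike-threshold criterion,
    input conductance from I-V steps, action-potential and after-hyperpolarization
    waveform metrics, immediate/delayed firing-pattern classification, detection of
    mixed-mode oscillations and sub-primary/primary range segmentation on slow
    triangular current ramps, SWC dendritic morphometry with a slice-plane
    inclusion rule, and the group-comparison statistics used to contrast wild-type
    and mSOD1 (G93A) motoneuron populations (Mann-Whitney, Fisher exact,
    Kolmogorov-Smirnov, zero-intercept rheobase-conductance regressions with slope
    t and Chow tests). Includes a synthetic motoneuron generator (template traces,
    a mechanistic leaky integrate-and-fire model with a slowly inactivating
    potassium conductance, and synthetic dendritic trees) providing ground truth
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    minpack.lm,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
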