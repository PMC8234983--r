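Package: threestate
Title: Three-State Protein Unfolding Equilibrium Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of three-state (native/intermediate/unfolded) protein
    unfolding equilibria monitored by tryptophan fluorescence and differential
    scanning calorimetry. Implements the linear extrapolation model for
    chemical (urea) denaturation and the Gibbs-Helmholtz model for thermal
    denaturation, with individual and global (replicate-shared) nonlinear
    least-squares fitting of sigmoidal unfolding curves with sloping linear
    baselines. Also provides van't Hoff deconvolution of two-transition DSC
    thermograms, fluorescence emission-spectrum descriptors (emission maximum,
    spectral shift, intensity ratios), sedimentation-coefficient
    standardization to water at 20 degrees C with frictional-ratio and
    c(s) peak-fraction computations, and a synthetic-data generator for all
    input types.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
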