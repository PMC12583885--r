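Package: dmiquant
Title: Quantitative Analysis of Deuterium Metabolic Imaging Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, denoising, prior-knowledge spectral fitting and
    quantification of dynamic deuterium (2H) magnetic resonance
    spectroscopic imaging of the human brain after ingestion of deuterated
    glucose. Provides anomer-resolved spectral prior models for
    [6,6'-2H2]- and [1,2,3,4,5,6,6'-2H7]glucose, Tucker-decomposition
    denoising of 4D chemical shift imaging tensors, AMARES-style
    constrained time-domain fitting of free induction decays,
    concentration estimation with internal water referencing and
    label-loss-corrected deuteron numbers, cohort time-course analysis,
    isotope label accounting, and steady-state flip-angle and Monte-Carlo
    SNR analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    RNifti,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
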