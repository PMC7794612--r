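Package: ventrack
Title: Cameraless Motion and Ventilation Analysis of Zebrafish from Electrode-Array Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring the emotional state of zebrafish from
    ventilatory bioelectric signals recorded by an electrode array at the
    bottom of an aquarium. Provides a synthetic virtual-aquarium simulator
    (state-dependent swimming and ventilation plus a forward model of the
    electrode signals), band-pass extraction and autoregressive spectral
    peak mapping, centre-of-gravity position estimation with spline
    interpolation, six motion and respiration indices computed in 5 s
    windows, the associated statistical battery (Welch t, one-way ANOVA,
    Cohen's d, PCA, Tukey-Kramer), and discrimination of normal,
    fear/anxiety and appetitive states with multi-class Fisher linear
    discriminant analysis and a log-linearised Gaussian mixture network
    under leave-one-fish-out cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
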