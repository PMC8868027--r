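Package: l7ephys
Title: E-Type Classification and Kv3 Current Analysis for Lamina VII
    Spinal Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for electrophysiological classification of spinal
    Lamina VII neurons and downstream analyses: action-potential
    detection and firing-pattern feature extraction from current-clamp
    sweeps, k-means e-typing with elbow selection and PCA projection,
    pulse-train fidelity, pharmacological (TEA/DTX) isolation of
    voltage-gated potassium currents with Boltzmann activation fitting
    and extra-sum-of-squares comparison, evoked/spontaneous postsynaptic
    current analysis (amplitude, paired-pulse ratio, train dynamics,
    distribution comparison), SWC neurite morphometrics (polar endpoint
    profiles, Sholl analysis, ventral-root-projection classification)
    and object-based puncta/bouton co-localization. Includes a synthetic
    data generator emulating four firing archetypes so that every stage
    is verifiable against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml,
    minpack.lm
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
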