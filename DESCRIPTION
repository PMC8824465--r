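Package: optomap
Title: Analysis of Synaptic Connectivity Mapped by Two-Photon Optogenetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing synaptic connectivity experiments in which
    candidate presynaptic neurons are activated one at a time by two-photon
    optogenetic stimulation while postsynaptic cells are recorded in whole-cell
    current clamp. Provides seeded generators for synthetic experiments
    (quantal synapses, photo-evoked spiking, membrane noise, labeled-cell point
    clouds, ground-truth networks), exponential-deconvolution detection and
    quantification of postsynaptic potentials, connection classification by
    support-vector machine or response z-scores, photostimulus spatial-resolution
    fitting, off-target activation estimation from labeled-cell densities,
    connection-probability statistics with Jeffreys intervals and exact
    contingency tests, bootstrap null models for convergence and divergence
    motifs, and intrinsic-electrophysiology feature extraction with interneuron
    clustering.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    mclust,
    minpack.lm,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
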