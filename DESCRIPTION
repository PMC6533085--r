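Package: synstp
Title: Simulation and Classification of Short-Term Plasticity at Unitary Synapses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying short-term plasticity (STP) at unitary
    glutamatergic synapses, modelled on granule-cell to molecular-layer-
    interneuron connections of the cerebellar cortex. Provides a stochastic
    quantal-release simulator (binomial release over a depleting, refilling
    pool of sites with probability facilitation and activity-dependent
    recruitment of reluctant vesicles), rendering of voltage-clamp sweeps
    with biexponential EPSC kernels, per-stimulus charge extraction and
    noise-referenced failure detection, minimal-stimulation quality control,
    min-max (vector space model) normalization with PCA and k-means
    classification of STP profiles including projection of a test cohort
    into a reference principal-component space, photostimulation analyses
    (binned charge time courses, peristimulus time histograms, latency
    coupling), and docked-vesicle/active-zone morphometry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
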