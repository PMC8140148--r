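Package: neuroact
Title: Quantification of Cortical Activity and Synapse Morphometry from
    Two-Photon, EM and Stereological Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying neuronal hyperactivity and synaptic
    structure in mouse cortex. Implements rigid per-frame motion correction of
    two-photon calcium movies, ROI and neuropil trace extraction with
    neuropil-contamination compensation (F_comp = F_ROI - r*F_np +
    r*median(F_np), r = 0.7), zero-phase low-pass filtering, rolling-percentile
    dF/F, robust-threshold calcium-transient detection with the 20-frame
    active-neuron criterion, electron-microscopy synapse morphometry (bouton
    area, active-zone length, vesicle-to-active-zone beeline distance,
    mitochondrion-based inhibitory classification), confocal puncta density
    with equivalent-diameter size filters, Cavalieri-principle volumetry with
    intracranial-volume normalization, laminar density profiles, and
    first-principles two-sample Kolmogorov-Smirnov and unpaired t tests. A
    synthetic-data module generates calcium movies, synapse geometries, puncta
    stacks and slice-area phantoms with known ground truth so that every stage
    is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    signal,
    tiff,
    jsonlite,
    yaml,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
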