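Package: geniculate
Title: Retinal Input Specialization and Visual Tuning of Thalamic Interneurons
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of the retinal inputs and visual response
    properties of inhibitory interneurons in the dorsolateral geniculate
    nucleus (dLGN). Implements Monte-Carlo occupancy statistics that score the
    cell-type specialization of rabies-traced presynaptic retinal ganglion
    cell (RGC) clusters; ChAT-band-referenced flattening of flat-mount retina
    stacks with stratification-based RGC typing; two-photon calcium imaging
    tuning analysis (circular-variance direction and orientation selectivity
    with permutation significance, suppressed-by-contrast classification);
    sparse-noise receptive-field mapping with shuffle-based significance; and
    dendrite-versus-soma feature correspondence with mono-exponential decay
    fits. A synthetic-data module generates all input kinds with known ground
    truth so every stage is testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    tiff,
    minpack.lm,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
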