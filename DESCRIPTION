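Package: nervearrow
Title: Optical Waveguide Model of the Myelinated Axon
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the myelinated nerve fiber as a depressed-core,
    anti-resonant reflecting optical waveguide (ARROW): a low-index axon
    wrapped in a high-index myelin annulus immersed in extracellular fluid.
    Provides a parametric geometry generator with biological imperfections
    (sinusoidal bend, cosine sheath-thickness variation, node of Ranvier),
    a semi-analytic scalar mode solver for the straight three-layer
    cylindrical fiber, a Fabry-Perot transverse-resonance analysis of the
    myelin annulus, a scalar split-step Fourier beam-propagation engine
    measuring axon-port and myelin-port transmission spectra, and pipeline
    helpers reproducing g-ratio and imperfection sweeps with ratio tables,
    crossing wavelengths and anti-resonant band edges.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
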