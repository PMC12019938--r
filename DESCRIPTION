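Package: HadamardScope
Title: Simulation and Reconstruction for Spectral Hadamard Microscopy
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for simulating and reconstructing metasurface-based
    spectral Hadamard microscopy. Constructs Paley-type Hadamard
    illumination codes and their self-similar pattern stacks, designs
    phase-only holograms of the illumination pattern by Gerchberg-Saxton
    iteration with Fraunhofer far-field propagation, models imaging,
    tissue-scattering (Monte Carlo) and spectrally dispersed point spread
    functions, simulates camera frame stacks for normal and spectral
    detection paths on synthetic multi-channel phantoms, and recovers
    optically sectioned and hyperspectral images through Hadamard decoding
    with digital pinhole and slit masks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3), methods
Imports: stats, EBImage, tiff, yaml, jsonlite, tools, utils
Suggests: testthat (>= 3.0.0), optparse
biocViews: Software, Microscopy, ImageProcessing, Spectroscopy
Config/testthat/edition: 3
RoxygenNote: 7.3.3
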