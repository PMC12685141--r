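Package: nanodimer
Title: Metrology and Simulation for Monomeric and Dimeric Gold-Nanoparticle Cryo-ET Labels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative analysis pipeline for gold-nanoparticle (AuNP)
    fiducial labels used in cryo-electron tomography, with a focus on
    discriminating monomeric particles from covalently bridged dimers.
    Provides synthetic-scene generators (2D class averages and 3D
    tomogram-like volumes with missing-wedge degradation and full ground
    truth), class-average metrology (radial intensity profiles, cutoff
    diameters, intercentroid separation histograms), small-angle X-ray
    scattering forward models and Moore-style indirect-transform inversion
    to the pair distance distribution function, linker and reach geometry,
    a transparent geometric monomer/dimer classifier for volumes with an
    evaluation harness, and label-to-membrane distance statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
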