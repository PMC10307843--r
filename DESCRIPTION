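Package: fflmpi
Title: Field-Free-Line Magnetic Particle Imaging Simulation and Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale digital twin of a portable human-sized interventional
    magnetic particle imaging (MPI) scanner that encodes 2D projections with a
    traveling field-free line (FFL). The package simulates the sinusoidal FFL
    trajectory, the Langevin nanoparticle signal with harmonic sideband
    analysis, line-wise gridding of the 1D induced signal into raw images,
    folding of the four redundant sub-images, and image-based system-matrix
    reconstruction with a regularized Kaczmarz solver, including multicontrast
    reconstruction with data subtraction. Deterministic phantom generators
    emulate dilution-series point samples, vascular tubes with adjustable
    stenosis grade and aneurysm bulges, pulsatile bolus injections, and
    marker-labeled endovascular instruments. Safety and operations calculators
    cover the magnetostimulation (PNS) threshold, SAR scaling, channel power,
    per-burst coil heating, convective cooling, and duty-cycle planning.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    jsonlite,
    tiff,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
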