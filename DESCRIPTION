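Package: pelletox
Title: Oxygen Supply Analysis and Reaction-Diffusion Modelling in Filamentous Fungal Pellets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify oxygen supply in submerged pellets of filamentous
    fungi. From 3D voxel images the package extracts shell-resolved hyphal
    volume fractions and shape metrics (sphericity, axis ratio, morphology
    number); microelectrode oxygen depth profiles are aligned with the image
    data on a common radial coordinate to yield penetration depths and the
    active part percentage. A 1D spherical reaction-diffusion model with
    hindered effective diffusivity and Monod consumption kinetics (with or
    without maintenance metabolism) simulates steady-state oxygen profiles,
    and per-pellet kinetic parameters such as the oxygen-related biomass
    yield are estimated by multistart bounded least squares with AICc model
    selection. A seeded synthetic-data module generates voxel phantoms and
    noisy oxygen profiles so the entire pipeline is testable without
    measured data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    tiff,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    EBImage
Config/testthat/edition: 3
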