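Package: callusim
Title: Multiscale Simulation of BMP-2-Treated Critical-Sized Bone Defect Healing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coupled agent-based and finite-element simulation of bone
    regeneration in a critical-sized femoral defect. A lattice agent-based
    model drives cell migration (chemotaxis-weighted random walks),
    proliferation, mechano-regulated differentiation and apoptosis; a
    reaction-diffusion model evolves the BMP-2 growth-factor field,
    including biexponential release from a collagen carrier sponge; and a
    simplified quasi-static poroelastic finite-element stage computes
    octahedral shear strain and interstitial fluid velocity, combined into
    the Prendergast differentiation stimulus. Tissue volume fractions are
    homogenized into element material properties and voxelized into
    microCT-style bone-volume (BV) outcomes for four treatment scenarios
    (control, weekly mechanical stimulation, BMP-2, and their combination).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
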