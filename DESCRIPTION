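Package: hygrobone
Title: Hygro-Elastic Finite Element Simulation of Swelling Bone Anchors and
    Strain-Energy-Driven Bone Remodeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale simulation of expansion-fit fixation by swelling
    co-polymeric bone anchors in trabecular bone. Provides a synthetic
    micro-CT generator with controlled bone volume ratio, Hounsfield-unit
    based calibration of apparent density and elastic modulus, a voxel-mesh
    linear-elastic finite element solver with hygroscopic eigenstrain
    loading, strain-energy-density driven bone remodeling with a lazy zone
    and overload resorption, bone-volume-ratio region-of-interest
    morphometry, and a Coulomb-friction push-out fixation estimate.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    tools,
    utils,
    tiff,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
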