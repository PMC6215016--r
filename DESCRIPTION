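Package: captureplan
Title: Thermal Neutron Capture Dose Enhancement Planning for Ion Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the dose enhancement obtainable by capturing
    the thermal neutrons generated internally during proton and carbon ion
    therapy. Provides a seeded synthetic pencil-beam kernel generator
    (per-primary physical dose and thermal neutron fluence on a voxel grid),
    a Bragg-peak-aligned energy-interpolated kernel library, RBE weighting to
    biological effective dose, non-negative least-squares optimization of
    spread-out-Bragg-peak energy weights for a flat target dose, accumulation
    of the resulting thermal neutron fluence, and the fluence-to-kerma
    arithmetic that converts neutron capture agent concentrations (boron-10
    and gadolinium-157 compounds) into tumour dose boosts and normal-tissue
    dose increases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    RNifti,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
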