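Package: proton4d
Title: 4D Dose Reconstruction for Scanned Proton Beams Under Cardiorespiratory Motion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates pencil-beam-scanning (PBS) proton delivery to a moving
    target and reconstructs the resulting 4D dose. Provides a synthetic 4D
    phantom with analytic respiratory and cardiac motion, motion-envelope
    (ITV/IRV) contouring, an analytic Bragg-curve dose engine on a 2-mm grid,
    a spot-by-spot beam-time model (energy-layer switching, spot switching,
    spot drilling), phase-wise plan splitting, deformable dose warping into
    4D accumulated and 4D dynamic doses, DVH-based plan-quality indices
    (Dx, Vx, Paddick conformity, homogeneity, gradient indices), and paired
    Wilcoxon signed-rank comparisons across synthetic cohorts to quantify
    dose blurring and interplay effects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
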