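Package: lvflow
Title: Left-Ventricular Cine-MRI Segmentation and Intraventricular Flow
    Energetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automatic left-ventricle (LV) lumen segmentation from cine
    cardiac magnetic-resonance image stacks (anisotropic diffusion, fuzzy
    c-means clustering, active-contour refinement), reconstruction of a moving
    LV geometry from the traced lumen-wall interface, finite-element simulation
    of incompressible Newtonian blood flow in the moving lumen with an
    arbitrary Lagrangian-Eulerian formulation and a zero-traction inlet-outlet
    boundary, and quantification of intraventricular flow energetics: kinetic
    energy density and averages, vorticity averages, hemodynamic force, flow
    rate, stroke volume and inlet-outlet power. Includes cine-like DICOM
    phantom generators with known ground truth and analytic moving-domain flow
    benchmarks for verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    EBImage,
    png,
    jsonlite,
    yaml,
    grDevices,
    graphics,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
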