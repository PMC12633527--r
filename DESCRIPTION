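Package: nervemap
Title: Fascicular Morphometry, Co-Registration, and Cuff-Electrode
    Stimulation Models of Peripheral Nerve
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for the computational stages of multi-modal peripheral
    nerve mapping: seeded synthetic nerve phantoms with ground truth,
    fascicular morphometry (effective circular diameters, perineurium
    thickness, split/merge detection, centerlines and transverse reslicing),
    two-tier binary-mask co-registration (metadata level-fraction mapping,
    rigid/similarity alignment and cubic B-spline refinement), nerve
    reshaping for cuff-electrode volume-conductor models (shrinkage
    inflation, area-preserving circularization with minimum-gap fascicle
    repacking), a finite-difference quasi-static Laplace solver with
    anisotropic conductivities, and McIntyre-Richardson-Grill double-cable
    axon simulation with bisection threshold search and dose-response
    (recruitment) curves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    EBImage,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
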