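Package: psmatrans
Title: Spatiotemporal Transport Modeling of Lu-177 PSMA Radioligand Therapy in Solid Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A voxel-based simulator of radiopharmaceutical delivery to solid
    tumors, built around Lu-177 labeled PSMA-617. Solves steady Darcy
    interstitial fluid flow with Starling transvascular exchange on labeled
    voxel phantoms, then integrates coupled convection-diffusion-reaction
    transport of radiolabeled (hot) and unlabeled (cold) ligand in free,
    receptor-bound and internalized compartments, together with PSMA receptor
    trafficking (synthesis, constitutive endocytosis, recycling,
    ligand-induced internalization, degradation). Plasma input supports bolus
    and continuous infusion. Post-processing provides time-integrated
    activity (TIA), AUC summaries, characteristic length/time scale
    diagnostics, and parameter-sweep experiments with tidy tabular output and
    ggplot2 visualisation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    methods,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    RNifti,
    deSolve,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
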