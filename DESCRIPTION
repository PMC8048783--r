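Package: p450nac
Title: Near-Attack-Conformation Scoring and Binding/Kinetics Analytics for
    P450 Steroid Hydroxylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometric reactivity analysis for cytochrome P450 compound I
    chemistry and the spectroscopic/kinetic assays that accompany it.
    Classifies near-attack conformations (NACs) of abstractable substrate
    hydrogens against the ferryl oxygen over multi-frame structures,
    computes per-site NAC percentages, shortest-distance and nearest-water
    traces with hydrogen-bond flags, and substrate mobility (RMSF).
    Fits type-I spin-shift titrations with the quadratic tight-binding
    (Morrison) equation, estimates high-spin fractions by linear unmixing,
    and converts spectrophotometric time courses into turnover numbers and
    NADH coupling efficiencies.  Superposes P450-steroid complexes (Kabsch)
    for C-alpha RMSD and ligand-atom correspondence distances.  Seeded
    synthetic-data generators emulate every input with ground-truth labels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
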