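Package: silafract
Title: Fractal-Cluster Metrics and NMR Observables for Peptide Self-Assembly Templates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis toolbox for supramolecular peptide/counterion assemblies
    that act as templates for biomimetic silica formation. Computes
    fractal-cluster metrics (radius of gyration, compactness, per-monomer
    contact valency, fractal dimension) from coarse-grained bead coordinates,
    NMR-derived observables (chemical shift perturbations, intensity ratios and
    residual dissolved fractions, per-residue silicification decay rates with
    surface/core classification, Stejskal-Tanner diffusion fits and
    Stokes-Einstein hydrodynamic radii), and small-angle scattering curves with
    Guinier and one-level Beaucage fits. Ships a synthetic-data generator that
    builds trimer-block assemblies of controlled morphology plus matching peak
    tables, DOSY decays and kinetic traces with known ground truth, so every
    analysis stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
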