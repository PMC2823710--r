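Package: perturbmap
Title: Automatic Mapping of Perturbed and Unperturbed Protein Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies protein residues as perturbed, unperturbed or
    ambiguous from per-residue perturbation data (for example NMR chemical
    shift perturbations) together with a three-dimensional structure or
    structure ensemble. Starting confidences in [-1, 1] are attributed by
    resampling sub-ensembles of the data against calibrated extreme
    standardized scores, residues without data are inferred by inverse
    distance weighting over structural neighbours through a sigmoidal
    distance kernel, and confidences are then iteratively homogenized over
    the residue contact graph until convergence, producing spatially
    coherent blocks. Includes interface extraction from complex structures,
    Matthews correlation scoring against a reference, classical
    threshold-based baselines, and a seeded generator of synthetic
    structures and perturbation datasets with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
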