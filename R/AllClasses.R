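#' @import methods
#' @importFrom stats rnorm runif sd setNames dist
#' @importFrom utils read.table write.table
#' @useDynLib perturbmap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Residue keys
#'
#' Residues are identified throughout the package by the string
#' \code{"<chain>:<number>"}, with any PDB insertion code appended to the
#' number (e.g. \code{"A:52"}, \code{"B:100A"}). This matches how NMR data
#' tables are indexed, so data tables and structures must share the same
#' chain identifiers and author residue numbering.
#'
#' @param chain character vector of chain identifiers.
#' @param resno integer (or character) vector of author residue numbers.
#' @param insert optional character vector of insertion codes (\code{""} or
#'   \code{NA} for none).
#' @return character vector of residue keys.
#' @examples
#' residueKey("A", 52)
#' residueKey(c("A", "B"), c(10, 100), c("", "A"))
#' @export
residueKey <- function(chain, resno, insert = "") {
    insert[is.na(insert)] <- ""
    paste0(chain, ":", resno, insert)
}

## ---------------------------------------------------------------------------
## StructureEnsemble
## ---------------------------------------------------------------------------

#' StructureEnsemble: one or more coordinate models of a protein
#'
#' Holds the atom records of a protein structure or NMR-style ensemble in a
#' single table with a \code{model} column. All models share the same residue
#' set (residues present in only some models are dropped on import). The
#' ensemble is the source of residue barycenters and of ensemble-averaged
#' inter-residue distances.
#'
#' @slot atoms data.frame with columns \code{model}, \code{key}, \code{chain},
#'   \code{resno}, \code{resid}, \code{elety}, \code{elesy}, \code{x},
#'   \code{y}, \code{z}; one row per atom per model. Hydrogens are flagged by
#'   \code{elesy == "H"}.
#' @slot keys character vector: the shared, ordered residue index.
#'
#' @seealso [readStructure()], [ensembleDistances()], [syntheticStructure()]
#' @export
setClass("StructureEnsemble",
    representation(atoms = "data.frame", keys = "character"))

setValidity("StructureEnsemble", function(object) {
    a <- object@atoms
    need <- c("model", "key", "chain", "resno", "resid", "elety", "elesy",
              "x", "y", "z")
    if (!all(need %in% names(a)))
        return(paste("atoms must have columns:", paste(need, collapse = ", ")))
    if (nrow(a) == 0L) return("ensemble contains no atoms")
    if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
        return("atom coordinates must be finite")
    for (m in unique(a$model)) {
        km <- unique(a$key[a$model == m])
        if (!setequal(km, object@keys))
            return(sprintf("model %s does not contain the shared residue set", m))
    }
    TRUE
})

## ---------------------------------------------------------------------------
## PerResidueData
## ---------------------------------------------------------------------------

#' PerResidueData: per-residue scalar perturbation values
#'
#' A map from residue keys to non-negative scalar perturbation values (e.g.
#' chemical shift perturbations, ppm-equivalent), plus an explicit set of
#' residues for which no measurement is available. Measured and missing keys
#' are disjoint; their union is the set of residues the user supplied.
#'
#' @slot values named numeric vector, names are residue keys; all values
#'   finite and >= 0.
#' @slot missing character vector of residue keys with no measurement.
#'
#' @seealso [readDataTable()], [computeCsp()], [perResidueData()]
#' @export
setClass("PerResidueData",
    representation(values = "numeric", missing = "character"))

setValidity("PerResidueData", function(object) {
    v <- object@values
    if (length(v) && is.null(names(v))) return("values must be named by residue key")
    if (anyDuplicated(names(v))) return("duplicate residue keys in values")
    if (anyDuplicated(object@missing)) return("duplicate residue keys in missing")
    if (length(v) && any(!is.finite(v))) return("values must be finite")
    if (length(v) && any(v < 0)) return("perturbation values must be non-negative")
    if (length(intersect(names(v), object@missing)))
        return("a residue cannot be both measured and missing")
    TRUE
})

#' Construct a PerResidueData object
#'
#' @param values named numeric vector of non-negative values (names are
#'   residue keys, see [residueKey()]).
#' @param missing character vector of residue keys without a measurement.
#' @return a [PerResidueData-class] object.
#' @examples
#' perResidueData(c("A:1" = 0.10, "A:3" = 0.02), missing = "A:2")
#' @export
perResidueData <- function(values = numeric(), missing = character()) {
    new("PerResidueData", values = values, missing = as.character(missing))
}

## ---------------------------------------------------------------------------
## SigmoidKernel
## ---------------------------------------------------------------------------

#' SigmoidKernel: the sigmoidal distance weighting function
#'
#' The kernel phi(d) = 1 / (1 + alphaEps * exp(lambda * d)) with
#' alphaEps = eps/(1 - eps) and lambda = (2/cutoff) * log((1 - eps)/eps),
#' so that phi(0) = 1 - eps, phi(cutoff) = eps and phi(cutoff/2) = 1/2
#' exactly. It weights a neighbour's contribution by its barycenter distance,
#' both when inferring missing residues and when homogenizing confidences.
#'
#' @slot cutoff numeric, neighbour cutoff distance c in Angstrom.
#' @slot epsilon numeric, the floor eps in (0, 0.5).
#' @slot alphaEps numeric, eps/(1-eps).
#' @slot lambda numeric, (2/c) * log((1-eps)/eps).
#'
#' @seealso [sigmoidKernel()], [phi()]
#' @export
setClass("SigmoidKernel",
    representation(cutoff = "numeric", epsilon = "numeric",
                   alphaEps = "numeric", lambda = "numeric"))

setValidity("SigmoidKernel", function(object) {
    if (length(object@cutoff) != 1L || object@cutoff <= 0)
        return("cutoff must be a single positive number")
    if (length(object@epsilon) != 1L ||
        object@epsilon <= 0 || object@epsilon >= 0.5)
        return("epsilon must lie in (0, 0.5)")
    TRUE
})

#' Construct a sigmoidal distance kernel
#'
#' @param cutoff neighbour cutoff distance in Angstrom (default 7.5).
#' @param epsilon kernel floor (default 1e-3): phi(0) = 1 - epsilon and
#'   phi(cutoff) = epsilon.
#' @return a [SigmoidKernel-class] object.
#' @examples
#' k <- sigmoidKernel()
#' phi(0, k)      # 0.999
#' phi(7.5, k)    # 0.001
#' phi(3.75, k)   # 0.5
#' @export
sigmoidKernel <- function(cutoff = 7.5, epsilon = 1e-3) {
    new("SigmoidKernel", cutoff = cutoff, epsilon = epsilon,
        alphaEps = epsilon / (1 - epsilon),
        lambda = (2 / cutoff) * log((1 - epsilon) / epsilon))
}

## ---------------------------------------------------------------------------
## MappingParams
## ---------------------------------------------------------------------------

#' MappingParams: tunable parameters of the mapping pipeline
#'
#' All tunables of the four-step classification in one object. Defaults are
#' the published operating point of the method: sub-ensembles of 15% of the
#' available data (floored at 3 values), roughly 1000 calibration runs and
#' 100 confidence trials per datum, a 7.5 Angstrom neighbour cutoff, a
#' sigmoid floor of 1e-3, homogenization convergence at RMSD < 1e-5, a
#' +/- 0.05 decision band, and a 25% relative-standard-deviation guard below
#' which data are deemed uninformative.
#'
#' @slot subsetFraction fraction of the data drawn into each sub-ensemble.
#' @slot calibMultiplier calibration runs per available datum.
#' @slot trialMultiplier confidence trials per available datum.
#' @slot neighborCutoff neighbour cutoff c, Angstrom.
#' @slot epsilon sigmoid kernel floor.
#' @slot homogTol homogenization convergence tolerance (RMSD between
#'   consecutive iterations).
#' @slot maxIter hard cap on homogenization iterations.
#' @slot decisionThreshold half-width of the ambiguous confidence band.
#' @slot sigmaRGuard relative-standard-deviation floor below which no
#'   classification is made.
#' @slot minSubsetSize minimum sub-ensemble size.
#' @slot seed integer RNG seed used by the pipeline.
#'
#' @seealso [mappingParams()], [mapPerturbations()]
#' @export
setClass("MappingParams",
    representation(subsetFraction = "numeric", calibMultiplier = "numeric",
                   trialMultiplier = "numeric", neighborCutoff = "numeric",
                   epsilon = "numeric", homogTol = "numeric",
                   maxIter = "integer", decisionThreshold = "numeric",
                   sigmaRGuard = "numeric", minSubsetSize = "integer",
                   seed = "integer"))

setValidity("MappingParams", function(object) {
    if (object@subsetFraction <= 0 || object@subsetFraction >= 1)
        return("subsetFraction must lie in (0, 1)")
    if (object@neighborCutoff <= 0) return("neighborCutoff must be positive")
    if (object@epsilon <= 0 || object@epsilon >= 0.5)
        return("epsilon must lie in (0, 0.5)")
    if (object@homogTol <= 0 || object@decisionThreshold <= 0 ||
        object@sigmaRGuard <= 0)
        return("tolerances and thresholds must be positive")
    if (object@calibMultiplier < 1 || object@trialMultiplier < 1)
        return("trial multipliers must be >= 1")
    if (object@minSubsetSize < 3L)
        return("minSubsetSize must be >= 3")
    TRUE
})

#' Construct pipeline parameters
#'
#' @param subsetFraction fraction of data per sub-ensemble (default 0.15).
#' @param calibMultiplier calibration runs per datum (default 1000).
#' @param trialMultiplier per-residue trials per datum (default 100).
#' @param neighborCutoff neighbour cutoff in Angstrom (default 7.5).
#' @param epsilon sigmoid floor (default 1e-3).
#' @param homogTol homogenization convergence RMSD (default 1e-5).
#' @param maxIter homogenization iteration cap (default 1e5).
#' @param decisionThreshold confidence cut for the final decision
#'   (default 0.05).
#' @param sigmaRGuard relative-SD floor (default 0.25).
#' @param minSubsetSize minimum sub-ensemble size (default 3).
#' @param seed RNG seed (default 1).
#' @return a [MappingParams-class] object.
#' @examples
#' mappingParams(seed = 7)
#' @export
mappingParams <- function(subsetFraction = 0.15, calibMultiplier = 1000,
                          trialMultiplier = 100, neighborCutoff = 7.5,
                          epsilon = 1e-3, homogTol = 1e-5, maxIter = 1e5,
                          decisionThreshold = 0.05, sigmaRGuard = 0.25,
                          minSubsetSize = 3, seed = 1) {
    new("MappingParams", subsetFraction = subsetFraction,
        calibMultiplier = calibMultiplier, trialMultiplier = trialMultiplier,
        neighborCutoff = neighborCutoff, epsilon = epsilon,
        homogTol = homogTol, maxIter = as.integer(maxIter),
        decisionThreshold = decisionThreshold, sigmaRGuard = sigmaRGuard,
        minSubsetSize = as.integer(minSubsetSize), seed = as.integer(seed))
}

## ---------------------------------------------------------------------------
## Calibration
## ---------------------------------------------------------------------------

#' Calibration: extreme standardized-score thresholds
#'
#' The thresholds kHigh (> 0) and kLow (< 0) obtained by resampling
#' sub-ensembles forced to contain the global maximum and minimum of the
#' data: kHigh is the lowest standardized score the maximum attains over all
#' runs, kLow the highest score the minimum attains. A datum whose
#' standardized score reaches kHigh (kLow) within a random sub-ensemble
#' contributes a full +1 (-1) confidence increment.
#'
#' @slot kHigh positive threshold mapped to confidence +1.
#' @slot kLow negative threshold mapped to confidence -1.
#' @seealso [calibrateExtremes()], [gammaTransform()]
#' @export
setClass("Calibration", representation(kHigh = "numeric", kLow = "numeric"))

setValidity("Calibration", function(object) {
    if (!(object@kLow < 0 && object@kHigh > 0))
        return("calibration requires kLow < 0 < kHigh")
    TRUE
})

## ---------------------------------------------------------------------------
## ConfidenceVector
## ---------------------------------------------------------------------------

#' ConfidenceVector: per-residue confidences with provenance
#'
#' Confidences rho in [-1, 1] (+1 = certainly perturbed, -1 = certainly
#' unperturbed) with a status per residue: \code{"measured"} (attributed by
#' resampling from the residue's own datum), \code{"inferred"} (interpolated
#' from structural neighbours), or \code{"excluded"} (no datum and fewer
#' than two measured neighbours; such residues carry \code{NA} confidence
#' and are dropped from all further computation).
#'
#' @slot rho named numeric vector of confidences; \code{NA} for excluded
#'   residues.
#' @slot status named character vector over the same keys, values in
#'   \code{c("measured", "inferred", "excluded")}.
#'
#' @seealso [attributeConfidences()], [inferMissing()],
#'   [homogenizeConfidences()]
#' @export
setClass("ConfidenceVector",
    representation(rho = "numeric", status = "character"))

setValidity("ConfidenceVector", function(object) {
    if (!identical(names(object@rho), names(object@status)))
        return("rho and status must share the same residue keys")
    if (!all(object@status %in% c("measured", "inferred", "excluded")))
        return("status must be measured, inferred or excluded")
    ex <- object@status == "excluded"
    r <- object@rho[!ex]
    if (length(r) && (any(is.na(r)) || any(r < -1 | r > 1)))
        return("non-excluded confidences must lie in [-1, 1]")
    if (any(!is.na(object@rho[ex])))
        return("excluded residues must carry NA confidence")
    TRUE
})

## ---------------------------------------------------------------------------
## ClassificationResult
## ---------------------------------------------------------------------------

#' ClassificationResult: the final per-residue classification
#'
#' The outcome of the full pipeline: one label per residue in
#' \code{c("perturbed", "unperturbed", "ambiguous", "no-decision")}, together
#' with the confidence vectors before and after homogenization, the
#' relative standard deviation of the input data, and whether the
#' flat-data guard fired (in which case every label is no-decision).
#'
#' @slot labels named character vector of labels.
#' @slot rhoStart [ConfidenceVector-class] before homogenization.
#' @slot rhoFinal [ConfidenceVector-class] after homogenization.
#' @slot sigmaR relative standard deviation sigma/mu of the measured data
#'   (NA when mu = 0).
#' @slot guardTriggered logical: sigmaR fell below the guard threshold.
#' @slot calibration the [Calibration-class] used (may be empty when the
#'   guard stopped the run).
#' @slot iterations integer, homogenization iterations performed.
#' @slot data the input [PerResidueData-class].
#'
#' @seealso [mapPerturbations()], [classifyResidues()], [writeResults()]
#' @export
setClass("ClassificationResult",
    representation(labels = "character", rhoStart = "ConfidenceVector",
                   rhoFinal = "ConfidenceVector", sigmaR = "numeric",
                   guardTriggered = "logical", calibration = "ANY",
                   iterations = "integer", data = "PerResidueData"))

setValidity("ClassificationResult", function(object) {
    ok <- c("perturbed", "unperturbed", "ambiguous", "no-decision")
    if (!all(object@labels %in% ok))
        return(paste("labels must be one of:", paste(ok, collapse = ", ")))
    if (isTRUE(object@guardTriggered) &&
        !all(object@labels == "no-decision"))
        return("guard-triggered results must be all no-decision")
    ex <- names(object@rhoFinal@status)[object@rhoFinal@status == "excluded"]
    if (length(ex) && !all(object@labels[ex] == "no-decision"))
        return("excluded residues must be labelled no-decision")
    TRUE
})

## ---------------------------------------------------------------------------
## ConfusionCounts
## ---------------------------------------------------------------------------

#' ConfusionCounts: a 2x2 confusion table
#'
#' @slot tp,fp,tn,fn non-negative integer counts.
#' @seealso [scorePrediction()], [matthewsCC()]
#' @export
setClass("ConfusionCounts",
    representation(tp = "integer", fp = "integer",
                   tn = "integer", fn = "integer"))

setValidity("ConfusionCounts", function(object) {
    n <- c(object@tp, object@fp, object@tn, object@fn)
    if (any(n < 0L)) return("counts must be non-negative")
    TRUE
})

#' Construct a confusion table
#'
#' @param tp,fp,tn,fn non-negative integer counts.
#' @return a [ConfusionCounts-class] object.
#' @examples
#' matthewsCC(confusionCounts(tp = 5, fp = 2, tn = 80, fn = 3))
#' @export
confusionCounts <- function(tp = 0, fp = 0, tn = 0, fn = 0) {
    new("ConfusionCounts", tp = as.integer(tp), fp = as.integer(fp),
        tn = as.integer(tn), fn = as.integer(fn))
}
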