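#' Residue keys of an object
#'
#' @param x an object holding per-residue information.
#' @return character vector of residue keys.
#' @export
setGeneric("residueKeys", function(x) standardGeneric("residueKeys"))

#' Number of models in a structure ensemble
#'
#' @param x a [StructureEnsemble-class].
#' @return integer model count.
#' @export
setGeneric("nModels", function(x) standardGeneric("nModels"))

#' Measured values of a per-residue dataset
#'
#' @param x a [PerResidueData-class] or [ClassificationResult-class].
#' @return named numeric vector of measured values.
#' @export
setGeneric("measuredValues", function(x) standardGeneric("measuredValues"))

#' Residues without a measurement
#'
#' @param x a [PerResidueData-class].
#' @return character vector of residue keys.
#' @export
setGeneric("missingResidues", function(x) standardGeneric("missingResidues"))

#' Per-residue confidences
#'
#' @param x a [ConfidenceVector-class] or [ClassificationResult-class].
#' @return named numeric vector of confidences in [-1, 1] (NA when excluded).
#' @export
setGeneric("confidences", function(x) standardGeneric("confidences"))

#' Per-residue provenance status
#'
#' @param x a [ConfidenceVector-class].
#' @return named character vector with values measured / inferred / excluded.
#' @export
setGeneric("residueStatus", function(x) standardGeneric("residueStatus"))

#' Final per-residue labels
#'
#' @param x a [ClassificationResult-class].
#' @return named character vector with values perturbed / unperturbed /
#'   ambiguous / no-decision.
#' @export
setGeneric("residueLabels", function(x) standardGeneric("residueLabels"))

#' @rdname residueKeys
setMethod("residueKeys", "StructureEnsemble", function(x) x@keys)
#' @rdname residueKeys
setMethod("residueKeys", "PerResidueData",
    function(x) c(names(x@values), x@missing))
#' @rdname residueKeys
setMethod("residueKeys", "ConfidenceVector", function(x) names(x@rho))
#' @rdname residueKeys
setMethod("residueKeys", "ClassificationResult", function(x) names(x@labels))

#' @rdname nModels
setMethod("nModels", "StructureEnsemble",
    function(x) length(unique(x@atoms$model)))

#' @rdname measuredValues
setMethod("measuredValues", "PerResidueData", function(x) x@values)
#' @rdname measuredValues
setMethod("measuredValues", "ClassificationResult",
    function(x) x@data@values)

#' @rdname missingResidues
setMethod("missingResidues", "PerResidueData", function(x) x@missing)

#' @rdname confidences
setMethod("confidences", "ConfidenceVector", function(x) x@rho)
#' @rdname confidences
setMethod("confidences", "ClassificationResult", function(x) x@rhoFinal@rho)

#' @rdname residueStatus
setMethod("residueStatus", "ConfidenceVector", function(x) x@status)

#' @rdname residueLabels
setMethod("residueLabels", "ClassificationResult", function(x) x@labels)

setMethod("show", "StructureEnsemble", function(object) {
    cat(sprintf("StructureEnsemble: %d residues, %d model(s), %d atoms/model\n",
        length(object@keys), nModels(object),
        sum(object@atoms$model == object@atoms$model[1])))
    ch <- unique(object@atoms$chain)
    cat("  chains:", paste(ch, collapse = ", "), "\n")
})

setMethod("show", "PerResidueData", function(object) {
    cat(sprintf("PerResidueData: %d measured, %d missing\n",
        length(object@values), length(object@missing)))
    if (length(object@values))
        cat(sprintf("  range [%.4g, %.4g], mean %.4g\n",
            min(object@values), max(object@values), mean(object@values)))
})

setMethod("show", "ConfidenceVector", function(object) {
    tab <- table(factor(object@status,
        levels = c("measured", "inferred", "excluded")))
    cat(sprintf(
        "ConfidenceVector: %d residues (%d measured, %d inferred, %d excluded)\n",
        length(object@rho), tab[["measured"]], tab[["inferred"]],
        tab[["excluded"]]))
    r <- object@rho[object@status != "excluded"]
    if (length(r))
        cat(sprintf("  rho range [%.3f, %.3f]\n", min(r), max(r)))
})

setMethod("show", "Calibration", function(object) {
    cat(sprintf("Calibration: kHigh = %.5f, kLow = %.5f\n",
        object@kHigh, object@kLow))
})

setMethod("show", "MappingParams", function(object) {
    cat("MappingParams:\n")
    cat(sprintf("  subsetFraction  %.2f   minSubsetSize %d\n",
        object@subsetFraction, object@minSubsetSize))
    cat(sprintf("  calibMultiplier %g   trialMultiplier %g\n",
        object@calibMultiplier, object@trialMultiplier))
    cat(sprintf("  neighborCutoff  %.2f A   epsilon %g\n",
        object@neighborCutoff, object@epsilon))
    cat(sprintf("  homogTol %g   decisionThreshold %.3f   sigmaRGuard %.2f\n",
        object@homogTol, object@decisionThreshold, object@sigmaRGuard))
    cat(sprintf("  seed %d\n", object@seed))
})

setMethod("show", "ClassificationResult", function(object) {
    cat("ClassificationResult\n")
    if (is.na(object@sigmaR)) {
        cat("  sigmaR: undefined (mean of data is zero)\n")
    } else {
        cat(sprintf("  sigmaR: %.1f%%%s\n", 100 * object@sigmaR,
            if (object@guardTriggered) " (guard triggered: no prediction)"
            else ""))
    }
    tab <- table(factor(object@labels, levels = c("perturbed", "unperturbed",
        "ambiguous", "no-decision")))
    cat(sprintf(
        "  labels: %d perturbed, %d unperturbed, %d ambiguous, %d no-decision\n",
        tab[["perturbed"]], tab[["unperturbed"]], tab[["ambiguous"]],
        tab[["no-decision"]]))
    if (!object@guardTriggered && is(object@calibration, "Calibration"))
        cat(sprintf("  kHigh %.4f, kLow %.4f; %d homogenization iterations\n",
            object@calibration@kHigh, object@calibration@kLow,
            object@iterations))
})

setMethod("show", "ConfusionCounts", function(object) {
    cat(sprintf("ConfusionCounts: tp=%d fp=%d tn=%d fn=%d (MCC %.3f)\n",
        object@tp, object@fp, object@tn, object@fn, matthewsCC(object)))
})
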