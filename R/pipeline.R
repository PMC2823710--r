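## The full four-step pipeline.

#' Map perturbed and unperturbed regions of a protein
#'
#' Runs the complete classification: the flat-data guard
#' ([relativeSD()]), calibration of the extreme standardized scores
#' ([calibrateExtremes()]), resampling attribution of starting confidences
#' ([attributeConfidences()]), inverse-distance-weighted inference of
#' residues without data ([inferMissing()]), iterative homogenization over
#' the contact graph ([homogenizeConfidences()]) and the final three-way
#' decision ([classifyResidues()]).
#'
#' The RNG is seeded from \code{params@seed} at entry, so identical inputs
#' and parameters give bit-identical results.
#'
#' When the relative standard deviation of the data falls below the guard
#' threshold the data are deemed indicative of an unperturbed protein: no
#' classification is attempted, every residue is labelled no-decision and
#' a warning is emitted. Passing \code{force = TRUE} overrides the guard
#' (the batch equivalent of answering an interactive "continue anyway?"
#' prompt); the result then records the low sigmaR but carries real
#' labels, and \code{guardTriggered} stays \code{FALSE} because the guard
#' did not stop the run.
#'
#' @param ens a [StructureEnsemble-class].
#' @param data a [PerResidueData-class]; every residue key must exist in
#'   the structure (numbering of the data table and of the PDB must
#'   agree).
#' @param params a [MappingParams-class].
#' @param force proceed even when the flat-data guard fires.
#' @param verbose log sigmaR, the calibration and the iteration count.
#' @return a [ClassificationResult-class].
#' @examples
#' ens <- syntheticStructure(nResidues = 60)
#' sim <- syntheticData(ens, seed = 3)
#' res <- mapPerturbations(ens, sim$data,
#'                         mappingParams(seed = 3, calibMultiplier = 100,
#'                                       trialMultiplier = 20))
#' res
#' @export
mapPerturbations <- function(ens, data, params = mappingParams(),
                             force = FALSE, verbose = FALSE) {
    unknown <- setdiff(residueKeys(data), ens@keys)
    if (length(unknown))
        stop("data table contains residue(s) absent from the structure: ",
             paste(utils::head(unknown, 5), collapse = ", "),
             if (length(unknown) > 5) " ..." else "",
             " (check that chain identifiers and numbering agree)")
    keys <- intersect(ens@keys, residueKeys(data))  # structure order
    say <- function(...) if (verbose) message(...)

    guard <- relativeSD(data, params@sigmaRGuard)
    say(sprintf("sigmaR = %s", if (is.na(guard$sigmaR)) "undefined"
                else sprintf("%.1f%%", 100 * guard$sigmaR)))
    if (guard$triggered && !force) {
        warning("relative standard deviation ",
                if (is.na(guard$sigmaR)) "undefined (zero mean)"
                else sprintf("%.1f%%", 100 * guard$sigmaR),
                " is below the ", sprintf("%.0f%%", 100 * params@sigmaRGuard),
                " guard: data look unperturbed, no classification made ",
                "(use force = TRUE to override)")
        emptyCV <- new("ConfidenceVector",
                       rho = setNames(numeric(0), character(0)),
                       status = setNames(character(0), character(0)))
        return(new("ClassificationResult",
            labels = setNames(rep("no-decision", length(keys)), keys),
            rhoStart = emptyCV, rhoFinal = emptyCV,
            sigmaR = guard$sigmaR, guardTriggered = TRUE,
            calibration = NULL, iterations = 0L, data = data))
    }

    set.seed(params@seed)
    kernel <- sigmoidKernel(params@neighborCutoff, params@epsilon)
    dmat <- ensembleDistances(ens)
    calib <- calibrateExtremes(data, params)
    say(sprintf("calibration: kHigh = %.4f, kLow = %.4f",
                calib@kHigh, calib@kLow))
    conf <- attributeConfidences(data, calib, params)
    conf <- inferMissing(conf, data, dmat, kernel)
    hom <- homogenizeConfidences(conf, dmat, kernel,
                                 tol = params@homogTol,
                                 maxIter = params@maxIter)
    iters <- attr(hom, "iterations")
    say(sprintf("homogenization converged in %d iterations", iters))
    labels <- classifyResidues(hom, params@decisionThreshold)
    say(sprintf("labels: %s", paste(names(table(labels)),
                table(labels), sep = "=", collapse = ", ")))
    reorder <- function(cv) new("ConfidenceVector", rho = cv@rho[keys],
                                status = cv@status[keys])
    new("ClassificationResult",
        labels = labels[keys],
        rhoStart = reorder(conf), rhoFinal = reorder(hom),
        sigmaR = guard$sigmaR, guardTriggered = FALSE,
        calibration = calib, iterations = iters, data = data)
}

#' Run the pipeline from files
#'
#' Thin file-level wrapper: reads a structure and either a per-residue
#' data table or a pair of free/bound chemical shift tables (combined via
#' [computeCsp()]), runs [mapPerturbations()] and writes the results TSV
#' (and optionally a confidence-coloured PDB).
#'
#' @param structurePath PDB file of the structure or ensemble.
#' @param dataPath per-residue data table (exclusive with the shift
#'   paths).
#' @param freeShiftsPath,boundShiftsPath shift tables of the two states.
#' @param outPath output TSV path.
#' @param pdbOutPath optional path for a PDB with confidences in the
#'   B-factor column.
#' @param params a [MappingParams-class].
#' @param weights spectral-width weights for [computeCsp()].
#' @param force,verbose passed to [mapPerturbations()].
#' @return the [ClassificationResult-class], invisibly.
#' @export
runPipeline <- function(structurePath, dataPath = NULL,
                        freeShiftsPath = NULL, boundShiftsPath = NULL,
                        outPath, pdbOutPath = NULL,
                        params = mappingParams(), weights = cspWeights(),
                        force = FALSE, verbose = FALSE) {
    if (is.null(dataPath) == is.null(freeShiftsPath))
        stop("provide either dataPath or both shift-table paths")
    if (!is.null(freeShiftsPath) && is.null(boundShiftsPath))
        stop("boundShiftsPath is required with freeShiftsPath")
    ens <- readStructure(structurePath)
    data <- if (!is.null(dataPath)) readDataTable(dataPath)
            else computeCsp(readShiftTable(freeShiftsPath),
                            readShiftTable(boundShiftsPath), weights)
    res <- mapPerturbations(ens, data, params, force = force,
                            verbose = verbose)
    if (!res@guardTriggered) writeResults(res, outPath)
    if (!is.null(pdbOutPath)) writeConfidencePDB(res, ens, pdbOutPath)
    invisible(res)
}
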