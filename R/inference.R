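## Step 2: inverse-distance-weighted inference of residues without data.

#' Infer confidences for residues without data
#'
#' Each residue without a measurement receives the phi-weighted mean of
#' the confidences of its measured structural neighbours within the kernel
#' cutoff (inverse distance weighting through the sigmoidal kernel):
#' \deqn{\rho_i = \sum_j \phi(d_{ij}) \rho_j \Big/ \sum_j \phi(d_{ij})}
#' A residue with fewer than two measured neighbours is excluded: it gets
#' status \code{"excluded"}, carries no confidence, and is dropped from all
#' further computation so that no decision is made about it. Inference is
#' single pass and only measured neighbours contribute, so the result does
#' not depend on the order in which missing residues are visited and
#' inferred values never seed other inferences.
#'
#' @param conf [ConfidenceVector-class] over the measured residues (from
#'   [attributeConfidences()]).
#' @param data the [PerResidueData-class] (supplies the missing set).
#' @param dmat distance matrix from [ensembleDistances()]; must cover all
#'   residues of \code{data}.
#' @param kernel a [SigmoidKernel-class].
#' @return a [ConfidenceVector-class] over measured + missing residues
#'   with statuses measured / inferred / excluded. Measured confidences are
#'   returned unchanged.
#' @export
inferMissing <- function(conf, data, dmat, kernel = sigmoidKernel()) {
    measured <- names(conf@rho)
    miss <- data@missing
    unknown <- setdiff(c(measured, miss), rownames(dmat))
    if (length(unknown))
        stop("residue(s) absent from the distance matrix: ",
             paste(unknown, collapse = ", "))
    rho <- conf@rho
    status <- conf@status
    for (i in miss) {
        nb <- neighborsWithin(i, dmat, kernel@cutoff)
        nb <- intersect(nb, measured)
        if (length(nb) < 2L) {
            rho[i] <- NA_real_
            status[i] <- "excluded"
        } else {
            w <- phi(dmat[i, nb], kernel)
            rho[i] <- sum(w * conf@rho[nb]) / sum(w)
            status[i] <- "inferred"
        }
    }
    new("ConfidenceVector", rho = rho, status = status)
}
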