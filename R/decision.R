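## Step 4: the flat-data guard and the final three-way decision.

#' Relative standard deviation of the measured data
#'
#' sigmaR = sigma / mu with mu and sigma the mean and population standard
#' deviation of all measured values. Data whose relative spread falls below
#' the guard threshold (default 25%) are considered indicative of an
#' unperturbed protein: the spread is mere noise around a common level and
#' any classification drawn from it would be spurious. All-zero data (mu =
#' 0) cannot be classified either; sigmaR is then NA and the guard fires.
#'
#' @param data a [PerResidueData-class] with at least 2 measured values.
#' @param guard relative-SD floor (default 0.25).
#' @return list with elements \code{sigmaR} (NA when mu = 0) and
#'   \code{triggered}.
#' @examples
#' relativeSD(perResidueData(c(A1 = 1, A2 = 2, A3 = 3)))  # ~40.8%, ok
#' @export
relativeSD <- function(data, guard = 0.25) {
    v <- data@values
    if (length(v) < 2L) stop("need at least 2 measured values")
    mu <- mean(v)
    if (mu <= 0) return(list(sigmaR = NA_real_, triggered = TRUE))
    sigmaR <- sqrt(mean((v - mu)^2)) / mu
    list(sigmaR = sigmaR, triggered = sigmaR < guard)
}

#' Classify residues from homogenized confidences
#'
#' Residues with confidence strictly above \code{+threshold} are labelled
#' perturbed, strictly below \code{-threshold} unperturbed, and in the
#' closed band in between ambiguous (possibly flanking or indirectly
#' affected by a perturbed region). Excluded residues are labelled
#' no-decision.
#'
#' @param conf a homogenized [ConfidenceVector-class].
#' @param threshold half-width of the ambiguous band (default 0.05).
#' @return named character vector of labels.
#' @export
classifyResidues <- function(conf, threshold = 0.05) {
    rho <- conf@rho
    lab <- ifelse(conf@status == "excluded", "no-decision",
           ifelse(rho > threshold, "perturbed",
           ifelse(rho < -threshold, "unperturbed", "ambiguous")))
    setNames(as.character(lab), names(rho))
}
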