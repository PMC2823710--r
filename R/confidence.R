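## Step 1: resampling attribution of starting confidences.
##
## Each residue's datum is repeatedly standardized within small random
## sub-ensembles of the data; the standardized scores are mapped onto
## [-1, 1] through thresholds calibrated on sub-ensembles forced to contain
## the global extremes. The hot loops live in src/resample.cpp and consume
## R's RNG, so a single set.seed() makes the whole step reproducible.

## sub-ensemble size: 15% of the available data by default, floored so the
## calibration subset can hold max + min + at least one random value
.subsetSize <- function(n, params) {
    min(n, max(params@minSubsetSize, round(params@subsetFraction * n)))
}

#' Standardized score of a value within a sub-ensemble
#'
#' k = (value - mu) / sigma with mu and sigma the population mean and
#' standard deviation of the sub-ensemble (which contains the value). A
#' sub-ensemble with zero spread gives no information; it is flagged
#' degenerate and k is NA.
#'
#' @param value the datum being scored.
#' @param subset numeric vector, the sub-ensemble (must contain
#'   \code{value}).
#' @return list with elements \code{mu}, \code{sigma}, \code{k} and
#'   \code{degenerate}.
#' @examples
#' kFactor(5, c(1, 2, 3, 4, 5))  # k = sqrt(2)
#' @export
kFactor <- function(value, subset) {
    if (length(subset) == 0L) stop("sub-ensemble must be non-empty")
    if (!any(abs(subset - value) < 1e-12))
        stop("sub-ensemble must contain the scored value")
    mu <- mean(subset)
    sigma <- sqrt(mean((subset - mu)^2))   # population convention
    deg <- sigma <= 1e-12 * max(1, abs(mu))
    list(mu = mu, sigma = sigma,
         k = if (deg) NA_real_ else (value - mu) / sigma,
         degenerate = deg)
}

#' Calibrate the extreme score thresholds
#'
#' Runs \code{calibMultiplier * N} resampling rounds. Each round draws a
#' sub-ensemble that always contains the global maximum and minimum of the
#' data plus randomly selected other values (without replacement), and
#' standardizes both extremes within it. kHigh is the lowest score the
#' maximum attains over all rounds and kLow the highest score of the
#' minimum: the least extreme scores the true extremes can show, so that
#' any datum scoring beyond them deserves full confidence. Rounds with zero
#' spread are skipped. When several residues tie for an extreme, one
#' representative carries the extreme per round; the tied others can still
#' be drawn as random members.
#'
#' @param data a [PerResidueData-class] with at least
#'   \code{minSubsetSize} measured values, not all equal.
#' @param params a [MappingParams-class].
#' @return a [Calibration-class]. The caller is responsible for seeding the
#'   RNG (see [mapPerturbations()]).
#' @examples
#' d <- perResidueData(setNames(c(rep(0, 9), 1), paste0("A:", 1:10)))
#' set.seed(1)
#' calibrateExtremes(d, mappingParams())   # kHigh ~ 1.414, kLow ~ -0.707
#' @export
calibrateExtremes <- function(data, params = mappingParams()) {
    v <- data@values
    n <- length(v)
    if (n < params@minSubsetSize)
        stop("calibration needs at least ", params@minSubsetSize,
             " measured values, got ", n)
    if (max(v) - min(v) <= 1e-12 * max(1, abs(mean(v))))
        stop("all measured values are (numerically) equal; ",
             "the data carry no classifiable signal")
    res <- .cppCalibrate(unname(v), as.integer(params@calibMultiplier * n),
                         .subsetSize(n, params))
    if (!is.finite(res[1]) || !is.finite(res[2]))
        stop("every calibration sub-ensemble was degenerate")
    new("Calibration", kHigh = res[1], kLow = res[2])
}

#' Map a standardized score to a confidence increment
#'
#' The clipped piecewise-linear transform Gamma: scores at or beyond the
#' calibrated extremes give +/-1, intermediate scores interpolate linearly
#' (k/kHigh for k >= 0, -k/kLow for k < 0), and degenerate sub-ensembles
#' (zero standard deviation, \code{k = NA}) contribute 0 because they are
#' not informative.
#'
#' @param k standardized score(s); NA marks a degenerate sub-ensemble.
#' @param calib a [Calibration-class].
#' @return numeric increment(s) in [-1, 1].
#' @export
gammaTransform <- function(k, calib) {
    out <- ifelse(is.na(k), 0,
           ifelse(k >= calib@kHigh, 1,
           ifelse(k <= calib@kLow, -1,
           ifelse(k >= 0, k / calib@kHigh, -k / calib@kLow))))
    as.numeric(out)
}

#' Attribute starting confidences by resampling
#'
#' For each measured residue i, repeats \code{trialMultiplier * N} trials:
#' draw a sub-ensemble containing the residue's own datum plus randomly
#' selected others, standardize the datum within it, and accumulate the
#' Gamma increment. The confidence rho_i is the accumulated sum divided by
#' the number of trials, hence always in [-1, 1]. Residues without data are
#' not part of the returned vector; they are added by [inferMissing()].
#'
#' @param data a [PerResidueData-class].
#' @param calib a [Calibration-class] from [calibrateExtremes()].
#' @param params a [MappingParams-class].
#' @return a [ConfidenceVector-class] over the measured residues, all with
#'   status \code{"measured"}.
#' @export
attributeConfidences <- function(data, calib, params = mappingParams()) {
    v <- data@values
    n <- length(v)
    if (n == 0L) stop("no measured values to attribute confidences to")
    rho <- .cppAttribute(unname(v), as.integer(params@trialMultiplier * n),
                         .subsetSize(n, params), calib@kHigh, calib@kLow)
    new("ConfidenceVector", rho = setNames(rho, names(v)),
        status = setNames(rep("measured", n), names(v)))
}
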