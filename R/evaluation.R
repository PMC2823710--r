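## Evaluation: reference interfaces from complex structures, Matthews
## correlation, the two classical threshold baselines, and scoring.

## squared cross-distances between two coordinate matrices
.crossDist2 <- function(a, b) {
    outer(rowSums(a^2), rep(1, nrow(b))) +
        outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * a %*% t(b)
}

#' Interface residues of a complex
#'
#' A residue of one subunit belongs to the interface if at least one of its
#' backbone atoms (N, CA, C, O) lies within \code{cutoff} of any
#' non-hydrogen atom of the other subunit, in at least one model of the
#' ensemble.
#'
#' @param ens a [StructureEnsemble-class] of the complex.
#' @param chainsA,chainsB disjoint, non-empty sets of chain identifiers
#'   defining the two subunits.
#' @param cutoff contact distance in Angstrom (default 5).
#' @return list with character-vector elements \code{a} and \code{b}: the
#'   interface residue keys of each subunit.
#' @export
interfaceResidues <- function(ens, chainsA, chainsB, cutoff = 5) {
    if (length(chainsA) == 0L || length(chainsB) == 0L)
        stop("both subunits need at least one chain")
    if (length(intersect(chainsA, chainsB)))
        stop("subunit chain sets must be disjoint")
    known <- unique(ens@atoms$chain)
    bad <- setdiff(c(chainsA, chainsB), known)
    if (length(bad)) stop("unknown chain(s): ", paste(bad, collapse = ", "))
    oneSide <- function(from, to) {
        hits <- character(0)
        for (m in unique(ens@atoms$model)) {
            a <- ens@atoms[ens@atoms$model == m, , drop = FALSE]
            bb <- a[a$chain %in% from & a$elety %in% .backboneNames &
                    a$elesy != "H", , drop = FALSE]
            other <- a[a$chain %in% to & a$elesy != "H", , drop = FALSE]
            if (nrow(bb) == 0L || nrow(other) == 0L) next
            d2 <- .crossDist2(as.matrix(bb[, c("x", "y", "z")]),
                              as.matrix(other[, c("x", "y", "z")]))
            contact <- apply(d2 <= cutoff^2, 1, any)
            hits <- union(hits, bb$key[contact])
        }
        intersect(ens@keys, hits)   # keep structure order
    }
    list(a = oneSide(chainsA, chainsB), b = oneSide(chainsB, chainsA))
}

#' Matthews correlation coefficient
#'
#' MCC = (tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn)); 1 for a
#' perfect prediction, 0 for a random one. When any marginal is empty the
#' denominator vanishes and the coefficient is returned as 0 with a
#' warning (the usual convention for degenerate tables).
#'
#' @param counts a [ConfusionCounts-class].
#' @return numeric in [-1, 1].
#' @examples
#' matthewsCC(confusionCounts(tp = 5, tn = 80, fp = 2, fn = 3))  # ~0.638
#' @export
matthewsCC <- function(counts) {
    tp <- as.numeric(counts@tp); fp <- as.numeric(counts@fp)
    tn <- as.numeric(counts@tn); fn <- as.numeric(counts@fn)
    den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
    if (den <= 0) {
        warning("degenerate confusion table; MCC reported as 0")
        return(0)
    }
    (tp * tn - fp * fn) / sqrt(den)
}

#' Single-pass threshold selection (baseline method A)
#'
#' The classical cutoff rule: residues whose value strictly exceeds the
#' mean of all measured data plus \code{nSigma} population standard
#' deviations are selected as perturbed. Mean and SD are computed once on
#' the full data.
#'
#' @param data a [PerResidueData-class] with >= 2 measured values.
#' @param nSigma 1 or 2.
#' @return character vector of selected residue keys.
#' @export
thresholdSelection <- function(data, nSigma = 1) {
    v <- data@values
    if (length(v) < 2L) stop("need at least 2 measured values")
    mu <- mean(v)
    sigma <- sqrt(mean((v - mu)^2))
    names(v)[v > mu + nSigma * sigma]
}

#' Iterative threshold selection (baseline method B)
#'
#' Repeatedly rejects values strictly above the mean plus \code{nSigma}
#' population standard deviations of the values still retained, recomputes
#' mean and SD on the remainder, and stops when no rejection occurs. All
#' rejected residues are returned as perturbed. Because each rejection
#' lowers the threshold, the selection always contains that of
#' [thresholdSelection()].
#'
#' @inheritParams thresholdSelection
#' @return character vector of selected residue keys.
#' @export
iterativeThresholdSelection <- function(data, nSigma = 1) {
    v <- data@values
    if (length(v) < 2L) stop("need at least 2 measured values")
    rejected <- character(0)
    repeat {
        if (length(v) < 2L) break
        mu <- mean(v)
        sigma <- sqrt(mean((v - mu)^2))
        out <- v > mu + nSigma * sigma
        if (!any(out)) break
        rejected <- c(rejected, names(v)[out])
        v <- v[!out]
    }
    rejected
}

#' Confusion counts of a predicted set against a reference set
#'
#' @param selected character vector of residue keys predicted positive.
#' @param truth character vector of true positive keys.
#' @param universe all residue keys being scored; \code{truth} must be a
#'   subset of it.
#' @return a [ConfusionCounts-class].
#' @export
scoreSelection <- function(selected, truth, universe) {
    if (length(truth) == 0L)
        stop("reference set is empty; MCC is undefined without positives")
    if (!all(truth %in% universe))
        stop("reference set must be contained in the scored universe")
    selected <- intersect(selected, universe)
    pos <- universe %in% truth
    sel <- universe %in% selected
    confusionCounts(tp = sum(sel & pos), fp = sum(sel & !pos),
                    tn = sum(!sel & !pos), fn = sum(!sel & pos))
}

#' Score a classification against a reference perturbed set
#'
#' Perturbed labels count as positive predictions and unperturbed as
#' negative. Ambiguous residues are counted according to
#' \code{ambiguousPolicy} (negative by default, or positive, or dropped
#' from the table altogether); no-decision residues are always dropped.
#'
#' @param result a [ClassificationResult-class].
#' @param truth character vector of reference perturbed residue keys.
#' @param ambiguousPolicy one of \code{"negative"}, \code{"positive"},
#'   \code{"drop"}.
#' @return a [ConfusionCounts-class].
#' @export
scorePrediction <- function(result, truth,
                            ambiguousPolicy = c("negative", "positive",
                                                "drop")) {
    ambiguousPolicy <- match.arg(ambiguousPolicy)
    lab <- result@labels[result@labels != "no-decision"]
    if (ambiguousPolicy == "drop") lab <- lab[lab != "ambiguous"]
    positive <- switch(ambiguousPolicy,
        negative = "perturbed", drop = "perturbed",
        positive = c("perturbed", "ambiguous"))
    scoreSelection(names(lab)[lab %in% positive],
                   intersect(truth, names(lab)), names(lab))
}

#' Benchmark the mapping pipeline against the threshold baselines
#'
#' Runs the full pipeline and baseline methods A and B (at 1 and 2 sigma)
#' on the same dataset and scores each against a reference perturbed set.
#' The pipeline is scored over its decided residues (ambiguous = negative,
#' no-decision dropped); the baselines are scored over all residues of the
#' dataset, residues without data counting as not selected since the
#' baselines cannot make a call on them.
#'
#' @param ens a [StructureEnsemble-class].
#' @param data a [PerResidueData-class].
#' @param truth character vector of reference perturbed residue keys.
#' @param params a [MappingParams-class].
#' @return data.frame with columns method, tp, fp, tn, fn, mcc.
#' @export
benchmarkMethods <- function(ens, data, truth, params = mappingParams()) {
    res <- mapPerturbations(ens, data, params)
    rows <- list()
    addRow <- function(method, counts) {
        rows[[length(rows) + 1L]] <<- data.frame(method = method,
            tp = counts@tp, fp = counts@fp, tn = counts@tn, fn = counts@fn,
            mcc = matthewsCC(counts), stringsAsFactors = FALSE)
    }
    addRow("mapping", scorePrediction(res, truth))
    universe <- residueKeys(data)
    for (ns in c(1, 2)) {
        addRow(sprintf("threshold_%dsd", ns),
               scoreSelection(thresholdSelection(data, ns), truth, universe))
        addRow(sprintf("iterative_%dsd", ns),
               scoreSelection(iterativeThresholdSelection(data, ns), truth,
                              universe))
    }
    do.call(rbind, rows)
}
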