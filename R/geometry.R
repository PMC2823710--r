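## Residue geometry: barycenters, ensemble-averaged distances, neighbour
## lookup and the sigmoidal distance kernel.

#' Residue barycenters of one model
#'
#' The unweighted mean of the atom coordinates of each residue. Hydrogens
#' are excluded by default: they are frequently absent from crystallographic
#' files, and including them when present would shift barycenters between
#' otherwise identical structures.
#'
#' @param ens a [StructureEnsemble-class].
#' @param model model number (default 1).
#' @param includeHydrogens logical; include H atoms in the mean.
#' @return numeric matrix, one row per residue (rownames are residue keys),
#'   columns x, y, z.
#' @export
residueBarycenters <- function(ens, model = 1L, includeHydrogens = FALSE) {
    a <- ens@atoms[ens@atoms$model == model, , drop = FALSE]
    if (nrow(a) == 0L) stop("no model ", model, " in ensemble")
    if (!includeHydrogens) {
        keep <- a$elesy != "H"
        ## a residue must keep at least one atom; all-hydrogen residues
        ## (not chemically sensible for proteins) fall back to all atoms
        drop0 <- setdiff(unique(a$key), unique(a$key[keep]))
        keep[a$key %in% drop0] <- TRUE
        a <- a[keep, , drop = FALSE]
    }
    xs <- rowsum(a[, c("x", "y", "z")], group = a$key)
    n <- as.vector(table(a$key)[rownames(xs)])
    bc <- as.matrix(xs / n)
    bc[ens@keys, , drop = FALSE]
}

#' Ensemble-averaged inter-residue distances
#'
#' For each model, the Euclidean distance between residue barycenters is
#' computed; the returned matrix is the per-pair average over all models,
#' which carries conformational heterogeneity of NMR-style ensembles into
#' the neighbour definition.
#'
#' @inheritParams residueBarycenters
#' @return symmetric numeric matrix (Angstrom) with zero diagonal, dimnames
#'   the residue keys.
#' @examples
#' ens <- syntheticStructure(nResidues = 20, seed = 1)
#' dm <- ensembleDistances(ens)
#' dm[1:3, 1:3]
#' @export
ensembleDistances <- function(ens, includeHydrogens = FALSE) {
    ms <- sort(unique(ens@atoms$model))
    acc <- NULL
    for (m in ms) {
        bc <- residueBarycenters(ens, m, includeHydrogens)
        d <- as.matrix(dist(bc))
        acc <- if (is.null(acc)) d else acc + d
    }
    dm <- acc / length(ms)
    dimnames(dm) <- list(ens@keys, ens@keys)
    dm
}

#' Structural neighbours of a residue
#'
#' All residues (any chain) whose ensemble-averaged barycenter distance to
#' the query is at most \code{cutoff}. The boundary is closed (a residue at
#' exactly the cutoff distance is a neighbour); the residue itself is not.
#'
#' @param key residue key.
#' @param dmat distance matrix from [ensembleDistances()].
#' @param cutoff distance cutoff in Angstrom (default 7.5).
#' @return character vector of neighbour residue keys.
#' @export
neighborsWithin <- function(key, dmat, cutoff = 7.5) {
    if (!key %in% rownames(dmat)) stop("unknown residue key: ", key)
    d <- dmat[key, ]
    names(d)[d <= cutoff & names(d) != key]
}

#' Sigmoidal distance weight
#'
#' Evaluates the kernel phi(d) = 1 / (1 + alphaEps * exp(lambda * d)) of a
#' [SigmoidKernel-class]. phi decreases strictly from 1 - epsilon at d = 0
#' to epsilon at the cutoff, crossing 1/2 at half the cutoff.
#'
#' @param d non-negative distance(s), Angstrom.
#' @param kernel a [SigmoidKernel-class] (default: cutoff 7.5, epsilon
#'   1e-3).
#' @return numeric weight(s) in (0, 1).
#' @examples
#' phi(c(0, 3.75, 7.5), sigmoidKernel())
#' @export
phi <- function(d, kernel = sigmoidKernel()) {
    if (any(d < 0)) stop("distances must be non-negative")
    1 / (1 + kernel@alphaEps * exp(kernel@lambda * d))
}

## phi weights of the neighbour graph: zero outside the cutoff and on the
## diagonal, phi(d) inside. Used by inference and homogenization.
.phiMatrix <- function(dmat, kernel) {
    w <- phi(dmat, kernel)
    w[dmat > kernel@cutoff] <- 0
    diag(w) <- 0
    w
}
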