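## Seeded generators of toy structures and perturbation datasets with a
## known ground truth. These power the end-to-end tests: a compact
## single-chain fold, a spatially contiguous perturbed patch with elevated
## signal, half-normal background noise, and a configurable fraction of
## missing data.

## evaluate expr under a given seed without disturbing the caller's RNG
.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv())) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(suppressWarnings(
            rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(seed)
    expr
}

#' Generate a synthetic single-chain structure
#'
#' One pseudo-atom per residue, so barycenters coincide with atom
#' positions and the geometry is fully controlled while the rest of the
#' pipeline treats the object exactly like a parsed PDB. \code{"helix"}
#' places residues on an ideal alpha-helical curve (1.5 Angstrom rise and
#' 100 degree turn per residue on a 2.3 Angstrom radius), giving a
#' constant consecutive-residue distance of about 3.83 Angstrom.
#' \code{"random_coil"} runs a self-avoiding random walk with 3.8 Angstrom
#' steps and a 3.0 Angstrom clash floor.
#'
#' @param nResidues number of residues (>= 10).
#' @param fold \code{"helix"} (default) or \code{"random_coil"}.
#' @param seed RNG seed (used by the coil walk; the helix is
#'   deterministic).
#' @param maxRetries restarts allowed for the self-avoiding walk.
#' @return a single-model, single-chain [StructureEnsemble-class] with
#'   residues A:1 ... A:nResidues.
#' @examples
#' syntheticStructure(nResidues = 30, seed = 1)
#' @export
syntheticStructure <- function(nResidues, fold = c("helix", "random_coil"),
                               seed = 1, maxRetries = 50) {
    fold <- match.arg(fold)
    if (nResidues < 10) stop("need at least 10 residues")
    if (fold == "helix") {
        i <- seq_len(nResidues) - 1
        theta <- i * 100 * pi / 180
        xyz <- cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i)
    } else {
        xyz <- .withSeed(seed, .selfAvoidingWalk(nResidues, maxRetries))
    }
    atoms <- data.frame(model = 1L,
        key = residueKey("A", seq_len(nResidues)), chain = "A",
        resno = seq_len(nResidues), resid = "ALA", elety = "CA",
        elesy = "C", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
        stringsAsFactors = FALSE)
    new("StructureEnsemble", atoms = atoms, keys = atoms$key)
}

.selfAvoidingWalk <- function(n, maxRetries, step = 3.8, clash = 3.0) {
    for (attempt in seq_len(maxRetries)) {
        xyz <- matrix(0, n, 3)
        ok <- TRUE
        for (i in 2:n) {
            placed <- FALSE
            for (try in 1:100) {
                u <- rnorm(3)
                cand <- xyz[i - 1, ] + step * u / sqrt(sum(u^2))
                prev <- xyz[seq_len(i - 2), , drop = FALSE]
                if (nrow(prev) == 0L ||
                    min(sqrt(rowSums(sweep(prev, 2, cand)^2))) >= clash) {
                    xyz[i, ] <- cand
                    placed <- TRUE
                    break
                }
            }
            if (!placed) { ok <- FALSE; break }
        }
        if (ok) return(xyz)
    }
    stop("self-avoiding walk failed after ", maxRetries, " restarts")
}

#' Generate a synthetic perturbation dataset with known ground truth
#'
#' Plants a spatially contiguous perturbed patch: the true perturbed set
#' is every residue whose barycenter lies within \code{patchRadius} of the
#' \code{patchCenter} residue. Perturbed residues draw
#' \code{effectSize + |N(0, noiseScale)|}, unperturbed residues
#' \code{|N(0, noiseScale)|} (half-normal noise keeps values non-negative
#' without truncation artifacts). A fraction of residues, chosen
#' uniformly, is then moved to the missing set. With \code{flat = TRUE}
#' the patch is suppressed and every residue scatters around a unit
#' baseline with standard deviation \code{noiseScale} (so
#' \code{noiseScale} is then the relative noise level), emulating an
#' unperturbed protein that should be caught by the [relativeSD()] guard.
#'
#' @param ens a [StructureEnsemble-class] (typically from
#'   [syntheticStructure()]).
#' @param patchCenter index (into the residue keys) of the patch centre
#'   (default: middle residue).
#' @param patchRadius patch radius in Angstrom (default 12).
#' @param effectSize mean value of perturbed residues (default 0.5).
#' @param noiseScale scale of the background noise (default 0.1, i.e. a
#'   5x signal-to-noise ratio at the defaults).
#' @param missingFraction fraction of residues without data, in [0, 0.5)
#'   (default 0.1).
#' @param flat logical: generate a patch-free flat-noise control instead.
#' @param seed RNG seed.
#' @return list with elements \code{data} (a [PerResidueData-class]) and
#'   \code{truth} (character vector of truly perturbed residue keys;
#'   empty when \code{flat}).
#' @examples
#' ens <- syntheticStructure(nResidues = 120)
#' sd1 <- syntheticData(ens, seed = 7)
#' length(sd1$truth)
#' @export
syntheticData <- function(ens, patchCenter = NULL, patchRadius = 12,
                          effectSize = 0.5, noiseScale = 0.1,
                          missingFraction = 0.1, flat = FALSE, seed = 1) {
    if (missingFraction < 0 || missingFraction >= 0.5)
        stop("missingFraction must lie in [0, 0.5)")
    if (!flat && (effectSize <= noiseScale || noiseScale <= 0))
        stop("need effectSize > noiseScale > 0")
    keys <- ens@keys
    n <- length(keys)
    if (is.null(patchCenter)) patchCenter <- round(n / 2)
    bc <- residueBarycenters(ens)
    d <- sqrt(rowSums(sweep(bc, 2, bc[patchCenter, ])^2))
    truth <- if (flat) character(0) else keys[d <= patchRadius]
    if (!flat && length(truth) > n / 2)
        stop("patch covers more than half the residues; ",
             "the benchmark would be ill-posed")
    .withSeed(seed, {
        if (flat) {
            values <- abs(rnorm(n, mean = 1, sd = noiseScale))
        } else {
            values <- abs(rnorm(n, sd = noiseScale))
            hit <- keys %in% truth
            values[hit] <- effectSize + values[hit]
        }
        names(values) <- keys
        nMiss <- floor(missingFraction * n)
        miss <- if (nMiss > 0) sample(keys, nMiss) else character(0)
        list(data = perResidueData(values = values[setdiff(keys, miss)],
                                   missing = miss),
             truth = truth)
    })
}
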