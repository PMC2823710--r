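## Chemical shift perturbations from free/bound shift tables.

.nuclei <- c("HN", "N", "CA", "CO")

#' Read a chemical shift table
#'
#' Reads a TSV/CSV table with columns chain, residue number, nucleus and
#' shift (ppm). Recognised nuclei are HN (amide proton), N (amide
#' nitrogen), CA (alpha carbon) and CO (carbonyl carbon); a residue may
#' carry any subset of them.
#'
#' @param path path to the table.
#' @return a data.frame with columns \code{key}, \code{nucleus},
#'   \code{ppm}.
#' @export
readShiftTable <- function(path) {
    if (!file.exists(path)) stop("cannot read shift table: ", path)
    sep <- .sniffSep(path)
    df <- utils::read.table(path, sep = sep, header = FALSE,
        col.names = c("chain", "seq_num", "nucleus", "ppm"),
        comment.char = "#", strip.white = TRUE,
        colClasses = c("character", "character", "character", "character"))
    if (nrow(df) && tolower(df$chain[1]) %in% c("chain", "chain_id"))
        df <- df[-1, , drop = FALSE]
    nuc <- toupper(df$nucleus)
    if (!all(nuc %in% .nuclei))
        stop("unrecognised nucleus label(s): ",
             paste(unique(nuc[!nuc %in% .nuclei]), collapse = ", "),
             " (expected ", paste(.nuclei, collapse = ", "), ")")
    ppm <- as.numeric(df$ppm)
    if (any(!is.finite(ppm))) stop("shift values must be finite numbers")
    out <- data.frame(key = residueKey(df$chain, df$seq_num), nucleus = nuc,
                      ppm = ppm, stringsAsFactors = FALSE)
    if (anyDuplicated(out[, c("key", "nucleus")]))
        stop("duplicate (residue, nucleus) entries in shift table")
    out
}

#' Spectral-width weights for combining nuclei
#'
#' Ratios that scale non-proton shift differences onto the amide-proton
#' scale before the Euclidean combination. The defaults (N 6.5, CA 10,
#' CO 10) are typical spectral-width ratios used in chemical shift
#' perturbation analysis; results on real shift tables are sensitive to
#' this choice, so the weights are explicit arguments rather than hidden
#' constants.
#'
#' @param swN spectral-width ratio HN/N (default 6.5).
#' @param swCA ratio HN/CA (default 10).
#' @param swCO ratio HN/CO (default 10).
#' @return named numeric vector of weights.
#' @export
cspWeights <- function(swN = 6.5, swCA = 10, swCO = 10) {
    w <- c(N = swN, CA = swCA, CO = swCO)
    if (any(w <= 0)) stop("spectral-width ratios must be positive")
    w
}

#' Combined chemical shift perturbation per residue
#'
#' For every residue present in both states with at least one nucleus in
#' common, computes
#' \deqn{CSP_i = \sqrt{\Delta H_N^2 + (\Delta N / SW_N)^2 +
#'   (\Delta C_\alpha / SW_{C\alpha})^2 + (\Delta C_O / SW_{CO})^2}}
#' over the nuclei available for that residue (a nucleus measured in only
#' one state contributes nothing). Residues absent from either table, or
#' with no common nucleus, are reported as missing so that their
#' confidence can later be inferred from the structure.
#'
#' @param free shift table of the reference state (from
#'   [readShiftTable()] or an equivalent data.frame).
#' @param bound shift table of the perturbed state.
#' @param weights spectral-width weights from [cspWeights()].
#' @return a [PerResidueData-class]; symmetric in the order of the two
#'   states.
#' @export
computeCsp <- function(free, bound, weights = cspWeights()) {
    need <- c("key", "nucleus", "ppm")
    stopifnot(all(need %in% names(free)), all(need %in% names(bound)))
    m <- merge(free, bound, by = c("key", "nucleus"),
               suffixes = c(".free", ".bound"))
    allKeys <- union(unique(free$key), unique(bound$key))
    if (nrow(m) == 0L)
        stop("no residue with a common nucleus in both shift tables")
    delta <- m$ppm.bound - m$ppm.free
    scale <- ifelse(m$nucleus == "HN", 1, weights[m$nucleus])
    contrib <- (delta / scale)^2
    ss <- rowsum(contrib, group = m$key)
    csp <- setNames(sqrt(ss[, 1]), rownames(ss))
    perResidueData(values = csp,
                   missing = setdiff(allKeys, names(csp)))
}
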