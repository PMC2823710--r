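## Structure and table input/output.
##
## PDB record parsing is delegated to bio3d; this layer handles ensemble
## bookkeeping (MODEL blocks, shared residue index, altloc resolution,
## HETATM policy) that bio3d's single-atom-table model cannot express when
## models disagree.

.backboneNames <- c("N", "CA", "C", "O")

## element symbol, falling back to the first alphabetic character of the
## atom name when the element column is blank (common in hand-made files)
.elementOf <- function(elety, elesy) {
    elesy <- toupper(trimws(as.character(elesy)))
    blank <- is.na(elesy) | elesy == ""
    if (any(blank)) {
        guess <- toupper(sub("^[0-9]*", "", trimws(elety[blank])))
        elesy[blank] <- substr(guess, 1L, 1L)
    }
    elesy
}

## one model's bio3d atom table -> tidy atom data.frame (altloc resolved,
## HETATM filtered)
.tidyModelAtoms <- function(atom, model, hetatmWhitelist) {
    keep <- atom$type == "ATOM" |
        (atom$type == "HETATM" & atom$resid %in% hetatmWhitelist)
    atom <- atom[keep, , drop = FALSE]
    if (nrow(atom) == 0L) return(NULL)
    key <- residueKey(atom$chain, atom$resno, atom$insert)
    alt <- atom$alt
    alt[is.na(alt)] <- ""
    occ <- atom$o
    occ[is.na(occ)] <- 1
    ## altloc: within each (residue, atom name), highest occupancy wins,
    ## ties broken by file order
    if (any(alt != "")) {
        grp <- paste(key, atom$elety)
        ord <- order(grp, -occ, seq_len(nrow(atom)))
        first <- !duplicated(grp[ord])
        sel <- sort(ord[first])
        atom <- atom[sel, , drop = FALSE]
        key <- key[sel]
    }
    data.frame(model = model, key = key, chain = atom$chain,
               resno = atom$resno, resid = atom$resid, elety = atom$elety,
               elesy = .elementOf(atom$elety, atom$elesy),
               x = atom$x, y = atom$y, z = atom$z,
               stringsAsFactors = FALSE)
}

#' Read a protein structure or ensemble from a PDB file
#'
#' Parses ATOM records (and whitelisted HETATM residues) into a
#' [StructureEnsemble-class]. MODEL/ENDMDL blocks become models. Alternate
#' locations are resolved to the highest-occupancy conformer (ties: first
#' listed). When models do not contain the same residue set, the
#' intersection is kept in every model, with a warning, so that the shared
#' residue index holds.
#'
#' @param path path to a PDB file.
#' @param modelPolicy \code{"all"} (default) keeps every model;
#'   \code{"first"} keeps only the first.
#' @param hetatmWhitelist character vector of 3-letter residue names whose
#'   HETATM records should be kept (default none: only protein ATOM
#'   records are read, so waters and ligands are excluded).
#' @return a [StructureEnsemble-class].
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' writeStructure(syntheticStructure(nResidues = 12, seed = 1), pdb)
#' readStructure(pdb)
#' @seealso [ensembleDistances()], [writeConfidencePDB()]
#' @export
readStructure <- function(path, modelPolicy = c("all", "first"),
                          hetatmWhitelist = character()) {
    modelPolicy <- match.arg(modelPolicy)
    if (!file.exists(path)) stop("cannot read structure file: ", path)
    lines <- readLines(path, warn = FALSE)
    starts <- grep("^MODEL", lines)
    chunks <- if (length(starts) == 0L) list(lines) else {
        ends <- c(starts[-1] - 1L, length(lines))
        mapply(function(s, e) lines[s:e], starts, ends, SIMPLIFY = FALSE)
    }
    if (modelPolicy == "first") chunks <- chunks[1]
    models <- list()
    for (m in seq_along(chunks)) {
        chunk <- chunks[[m]]
        if (!any(grepl("^(ATOM|HETATM)", chunk))) next
        tf <- tempfile(fileext = ".pdb")
        on.exit(unlink(tf), add = TRUE)
        writeLines(chunk, tf)
        ## rm.alt = FALSE: altloc resolution (occupancy-based) is ours
        pdb <- tryCatch(suppressWarnings(
                bio3d::read.pdb(tf, verbose = FALSE, rm.alt = FALSE)),
                        error = function(e)
                            stop("failed to parse PDB file '", path, "': ",
                                 conditionMessage(e)))
        tidy <- .tidyModelAtoms(pdb$atom, length(models) + 1L,
                                hetatmWhitelist)
        if (!is.null(tidy)) models[[length(models) + 1L]] <- tidy
    }
    if (length(models) == 0L)
        stop("no protein residues found in ", path)
    keySets <- lapply(models, function(a) unique(a$key))
    shared <- Reduce(intersect, keySets)
    if (length(shared) == 0L)
        stop("models share no residues in ", path)
    if (!all(vapply(keySets, function(k) setequal(k, shared), logical(1)))) {
        warning("models differ in residue content; keeping the ",
                length(shared), " residues common to all models")
        models <- lapply(models, function(a) a[a$key %in% shared, ,
                                               drop = FALSE])
    }
    atoms <- do.call(rbind, models)
    rownames(atoms) <- NULL
    ## shared index in the order of first appearance in model 1
    keys <- unique(atoms$key[atoms$model == 1L])
    new("StructureEnsemble", atoms = atoms, keys = keys)
}

#' Write a structure ensemble to a PDB file
#'
#' @param ens a [StructureEnsemble-class].
#' @param path output path.
#' @param b optional named numeric vector (by residue key) written into the
#'   B-factor column of every atom of that residue; defaults to 0.
#' @return invisibly, \code{path}.
#' @export
writeStructure <- function(ens, path, b = NULL) {
    a <- ens@atoms
    nm <- sort(unique(a$model))
    multi <- length(nm) > 1L
    con <- file(path, "w")
    on.exit(close(con))
    for (m in nm) {
        am <- a[a$model == m, , drop = FALSE]
        bf <- rep(0, nrow(am))
        if (!is.null(b)) {
            hit <- am$key %in% names(b)
            bf[hit] <- b[am$key[hit]]
        }
        if (multi) writeLines(sprintf("MODEL     %4d", m), con)
        tf <- tempfile(fileext = ".pdb")
        bio3d::write.pdb(file = tf,
            xyz = as.numeric(t(as.matrix(am[, c("x", "y", "z")]))),
            type = rep("ATOM", nrow(am)), resno = am$resno,
            resid = am$resid, chain = am$chain,
            eleno = seq_len(nrow(am)), elety = am$elety,
            o = rep(1, nrow(am)), b = bf, elesy = am$elesy)
        rec <- readLines(tf, warn = FALSE)
        unlink(tf)
        writeLines(grep("^(ATOM|HETATM|TER)", rec, value = TRUE), con)
        if (multi) writeLines("ENDMDL", con)
    }
    writeLines("END", con)
    invisible(path)
}

#' Write a PDB with confidences in the B-factor column
#'
#' Copies the structure with each residue's final confidence written into
#' the B-factor of all its atoms, for colouring in molecular viewers.
#' Residues without a decision get B = 0.
#'
#' @param result a [ClassificationResult-class].
#' @param ens the [StructureEnsemble-class] the result was computed on.
#' @param path output PDB path.
#' @return invisibly, \code{path}.
#' @export
writeConfidencePDB <- function(result, ens, path) {
    rho <- result@rhoFinal@rho
    rho[is.na(rho)] <- 0
    writeStructure(ens, path, b = rho)
}

.sniffSep <- function(path) {
    first <- readLines(path, n = 25L, warn = FALSE)
    first <- first[!grepl("^#", first) & nzchar(first)]
    if (length(first) && any(grepl(",", first[1]))) "," else ""
}

#' Read a per-residue data table
#'
#' Reads a TSV/CSV table with columns chain, residue number and value (a
#' header line is optional; comma or whitespace separated). An empty value
#' or the sentinel \code{NA} marks a residue as missing.
#'
#' @param path path to the table.
#' @return a [PerResidueData-class].
#' @details Values must be non-negative (perturbation magnitudes) and each
#'   (chain, residue number) key may appear only once; violations are
#'   errors, not silently repaired.
#' @export
readDataTable <- function(path) {
    if (!file.exists(path)) stop("cannot read data table: ", path)
    sep <- .sniffSep(path)
    df <- utils::read.table(path, sep = sep, header = FALSE,
        col.names = c("chain", "seq_num", "value"), comment.char = "#",
        colClasses = c("character", "character", "character"),
        strip.white = TRUE, fill = TRUE, blank.lines.skip = TRUE)
    if (nrow(df) && tolower(df$chain[1]) %in% c("chain", "chain_id"))
        df <- df[-1, , drop = FALSE]
    if (nrow(df) == 0L) stop("data table is empty: ", path)
    key <- residueKey(df$chain, df$seq_num)
    if (anyDuplicated(key))
        stop("duplicate residue key(s) in data table: ",
             paste(unique(key[duplicated(key)]), collapse = ", "))
    raw <- df$value
    isMissing <- is.na(raw) | raw == "" | toupper(raw) == "NA"
    val <- suppressWarnings(as.numeric(raw[!isMissing]))
    if (any(is.na(val)))
        stop("non-numeric value(s) in data table: ",
             paste(raw[!isMissing][is.na(val)], collapse = ", "))
    if (any(val < 0))
        stop("negative value(s) in data table; perturbation magnitudes ",
             "must be non-negative")
    perResidueData(values = setNames(val, key[!isMissing]),
                   missing = key[isMissing])
}

.splitKey <- function(key) {
    pos <- regexpr(":", key, fixed = TRUE)
    data.frame(chain = substr(key, 1L, pos - 1L),
               seq_num = substr(key, pos + 1L, nchar(key)),
               stringsAsFactors = FALSE)
}

.fmtNum <- function(x) ifelse(is.na(x), "", sprintf("%.6f", x))

#' Write classification results to a TSV file
#'
#' One row per residue with columns chain, seq_num, input_value, rho_start,
#' rho_final, status and label. Header comment lines record the relative
#' standard deviation of the input and whether the flat-data guard fired.
#' Excluded residues have empty confidence fields and label no-decision.
#'
#' @param result a [ClassificationResult-class].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @seealso [readResults()] for the inverse.
#' @export
writeResults <- function(result, path) {
    keys <- names(result@labels)
    kp <- .splitKey(keys)
    v <- rep(NA_real_, length(keys))
    hit <- keys %in% names(result@data@values)
    v[hit] <- result@data@values[keys[hit]]
    pick <- function(x) {
        out <- x[keys]
        if (is.character(out)) out[is.na(out)] <- ""
        out
    }
    df <- data.frame(chain = kp$chain, seq_num = kp$seq_num,
        input_value = .fmtNum(v),
        rho_start = .fmtNum(pick(result@rhoStart@rho)),
        rho_final = .fmtNum(pick(result@rhoFinal@rho)),
        status = pick(result@rhoFinal@status),
        label = result@labels[keys], stringsAsFactors = FALSE)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# sigma_r\t%s", .fmtNum(result@sigmaR)), con)
    writeLines(sprintf("# guard_triggered\t%s",
        tolower(as.character(result@guardTriggered))), con)
    writeLines(paste(names(df), collapse = "\t"), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read back a results TSV
#'
#' Re-reads a file written by [writeResults()] into a
#' [ClassificationResult-class] (confidences at the 6-decimal precision of
#' the file; the calibration is not stored in the file and comes back
#' empty).
#'
#' @param path path to a results TSV.
#' @return a [ClassificationResult-class].
#' @export
readResults <- function(path) {
    if (!file.exists(path)) stop("cannot read results file: ", path)
    hdr <- readLines(path, n = 2L, warn = FALSE)
    sigmaR <- suppressWarnings(as.numeric(sub("^# sigma_r\t", "", hdr[1])))
    guard <- identical(sub("^# guard_triggered\t", "", hdr[2]), "true")
    df <- utils::read.table(path, sep = "\t", header = TRUE,
        comment.char = "#", colClasses = "character")
    keys <- residueKey(df$chain, df$seq_num)
    num <- function(x) suppressWarnings(as.numeric(ifelse(x == "", NA, x)))
    vals <- num(df$input_value)
    cv <- function(rho) {
        if (all(df$status == ""))  # guard-triggered run: no confidences
            return(new("ConfidenceVector", rho = setNames(numeric(0),
                character(0)), status = setNames(character(0), character(0))))
        new("ConfidenceVector",
            rho = setNames(rho, keys), status = setNames(df$status, keys))
    }
    new("ClassificationResult",
        labels = setNames(df$label, keys),
        rhoStart = cv(num(df$rho_start)), rhoFinal = cv(num(df$rho_final)),
        sigmaR = sigmaR, guardTriggered = guard, calibration = NULL,
        iterations = 0L,
        data = perResidueData(values = setNames(vals[!is.na(vals)],
                                                keys[!is.na(vals)]),
                              missing = keys[is.na(vals)]))
}
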