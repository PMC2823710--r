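# Fixtures are built in code: raw PDB record strings for parser tests and
# programmatic StructureEnsemble objects for geometry/evaluation tests.

pdbLine <- function(serial, name, resn, chain, resno, x, y, z,
                    elem = substr(name, 1, 1), alt = "", icode = "",
                    occ = 1, b = 0, type = "ATOM") {
    sprintf("%-6s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            type, serial, sprintf(" %-3s", name), alt, resn, chain, resno,
            icode, x, y, z, occ, b, elem)
}

writePdbFixture <- function(lines, path = tempfile(fileext = ".pdb")) {
    writeLines(c(lines, "END"), path)
    path
}

# a three-residue single-model chain along x
threeResidueLines <- function() {
    c(pdbLine(1, "N", "ALA", "A", 1, 0, 0, 0, "N"),
      pdbLine(2, "CA", "ALA", "A", 1, 1, 0, 0, "C"),
      pdbLine(3, "CA", "GLY", "A", 2, 4, 0, 0, "C"),
      pdbLine(4, "CA", "SER", "A", 3, 8, 0, 0, "C"))
}

# build a StructureEnsemble directly from per-atom vectors
makeEns <- function(model, chain, resno, elety, elesy, x, y, z,
                    resid = "ALA") {
    key <- residueKey(chain, resno)
    atoms <- data.frame(model = as.integer(model), key = key, chain = chain,
                        resno = resno, resid = resid, elety = elety,
                        elesy = elesy, x = x, y = y, z = z,
                        stringsAsFactors = FALSE)
    new("StructureEnsemble", atoms = atoms,
        keys = unique(atoms$key[atoms$model == min(atoms$model)]))
}

# single-model ensemble of point residues (one pseudo-atom each)
pointEns <- function(xyz, chain = "A") {
    n <- nrow(xyz)
    makeEns(model = rep(1L, n), chain = rep(chain, n), resno = seq_len(n),
            elety = rep("CA", n), elesy = rep("C", n),
            x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
}

# named confidence vector helper
makeCV <- function(rho, status = rep("measured", length(rho))) {
    new("ConfidenceVector", rho = rho,
        status = stats::setNames(status, names(rho)))
}

# the deterministic calibration dataset: nine zeros and a single one
nineZerosOneOne <- function() {
    perResidueData(stats::setNames(c(rep(0, 9), 1), paste0("A:", 1:10)))
}

expect_setequal_chr <- function(a, b) expect_true(setequal(a, b))
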