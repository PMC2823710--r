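test_that("helix geometry matches the closed-form chord lengths", {
    ens <- syntheticStructure(10)
    dm <- ensembleDistances(ens)
    ## chord of a 1.5 A rise and a 100 degree arc on a 2.3 A radius
    chord1 <- sqrt(1.5^2 + (2 * 2.3 * sin(50 * pi / 180))^2)
    consec <- dm[cbind(1:9, 2:10)]
    expect_equal(consec, rep(chord1, 9), tolerance = 1e-9)
    ## i,i+1 is closer than i,i+3 for these helix parameters
    chord3 <- sqrt((3 * 1.5)^2 + (2 * 2.3 * sin(150 * pi / 180))^2)
    expect_equal(dm[1, 4], chord3, tolerance = 1e-9)
    expect_lt(chord1, chord3)
})

test_that("structure generation is deterministic per seed and validated", {
    c1 <- syntheticStructure(20, fold = "random_coil", seed = 5)
    c2 <- syntheticStructure(20, fold = "random_coil", seed = 5)
    expect_identical(c1@atoms, c2@atoms)
    c3 <- syntheticStructure(20, fold = "random_coil", seed = 6)
    expect_false(identical(c1@atoms, c3@atoms))
    expect_error(syntheticStructure(5), "at least 10")
})

test_that("coil walks keep the step length and avoid clashes", {
    for (s in 1:3) {
        ens <- syntheticStructure(30, fold = "random_coil", seed = s)
        xyz <- as.matrix(ens@atoms[, c("x", "y", "z")])
        steps <- sqrt(rowSums((xyz[-1, ] - xyz[-30, ])^2))
        expect_equal(steps, rep(3.8, 29), tolerance = 1e-9)
        dm <- as.matrix(dist(xyz))
        offdiag <- dm[upper.tri(dm)]
        expect_gte(min(offdiag), 3.0 - 1e-9)
    }
})

test_that("the planted patch is spatially and sequentially contiguous", {
    ens <- syntheticStructure(120)
    sim <- syntheticData(ens, patchCenter = 60, patchRadius = 12, seed = 1)
    idx <- match(sim$truth, residueKeys(ens))
    expect_equal(idx, seq(min(idx), max(idx)))   # contiguous interval
    expect_true(60 %in% idx)
    ## every truth residue is within the radius, all others outside
    bc <- residueBarycenters(ens)
    d <- sqrt(rowSums(sweep(bc, 2, bc[60, ])^2))
    expect_setequal_chr(sim$truth, residueKeys(ens)[d <= 12])
})

test_that("signal separates from noise in the near-noiseless limit", {
    ens <- syntheticStructure(60)
    sim <- syntheticData(ens, effectSize = 0.5, noiseScale = 1e-6,
                         missingFraction = 0, seed = 2)
    v <- measuredValues(sim$data)
    expect_length(v, 60)   # no missing data
    expect_gt(min(v[sim$truth]), max(v[setdiff(names(v), sim$truth)]))
})

test_that("missing residues are carved out of the measured set", {
    ens <- syntheticStructure(50)
    sim <- syntheticData(ens, missingFraction = 0.2, seed = 9)
    expect_length(missingResidues(sim$data), 10)
    expect_length(measuredValues(sim$data), 40)
    expect_setequal_chr(residueKeys(sim$data), residueKeys(ens))
})

test_that("ill-posed patches and noise settings are rejected", {
    ens <- syntheticStructure(20)
    expect_error(syntheticData(ens, patchRadius = 100), "half the residues")
    expect_error(syntheticData(ens, effectSize = 0.1, noiseScale = 0.2),
                 "effectSize > noiseScale")
    expect_error(syntheticData(ens, missingFraction = 0.7), "0.5")
})

test_that("planted-patch data clear the guard; flat controls trigger it", {
    ens <- syntheticStructure(120)
    trig <- 0L
    for (s in 1:20) {
        sim <- syntheticData(ens, seed = s)   # effect 5x noise, ~12% patch
        expect_false(relativeSD(sim$data)$triggered)
        flat <- syntheticData(ens, flat = TRUE, noiseScale = 0.05, seed = s)
        trig <- trig + relativeSD(flat$data)$triggered
    }
    expect_gte(trig, 19L)
})
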