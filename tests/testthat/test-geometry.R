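test_that("residue barycenters are unweighted means of heavy-atom coordinates", {
    one <- makeEns(1L, "A", 1L, "CA", "C", 1, 2, 3)
    expect_equal(unname(residueBarycenters(one)[1, ]), c(1, 2, 3))

    two <- makeEns(rep(1L, 2), rep("A", 2), rep(1L, 2), c("CA", "CB"),
                   c("C", "C"), c(0, 2), c(0, 0), c(0, 0))
    expect_equal(unname(residueBarycenters(two)[1, ]), c(1, 0, 0))

    basis <- makeEns(rep(1L, 3), rep("A", 3), rep(1L, 3),
                     c("N", "CA", "C"), c("N", "C", "C"),
                     c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
    expect_equal(unname(residueBarycenters(basis)[1, ]), rep(1 / 3, 3))
})

test_that("hydrogens are excluded from barycenters by default", {
    ens <- makeEns(rep(1L, 2), rep("A", 2), rep(1L, 2), c("CA", "HA"),
                   c("C", "H"), c(0, 10), c(0, 0), c(0, 0))
    expect_equal(unname(residueBarycenters(ens)[1, 1]), 0)
    expect_equal(unname(
        residueBarycenters(ens, includeHydrogens = TRUE)[1, 1]), 5)
})

test_that("ensemble distances average the per-model barycenter distances", {
    e1 <- pointEns(rbind(c(0, 0, 0), c(3, 4, 0)))
    dm <- ensembleDistances(e1)
    expect_equal(dm["A:1", "A:2"], 5)
    expect_equal(diag(dm), c("A:1" = 0, "A:2" = 0))

    ## model distances 4 and 6 average to 5
    a2 <- e1@atoms; a2$model <- 2L; a2$x <- c(0, 6); a2$y <- 0
    a1 <- e1@atoms; a1$x <- c(0, 4); a1$y <- 0
    ens <- new("StructureEnsemble", atoms = rbind(a1, a2), keys = e1@keys)
    expect_equal(ensembleDistances(ens)["A:1", "A:2"], 5)
})

test_that("single-model ensemble distances equal plain pairwise distances", {
    ens <- syntheticStructure(15)
    bc <- residueBarycenters(ens)
    oracle <- as.matrix(dist(bc))
    dm <- ensembleDistances(ens)
    expect_equal(unname(dm), unname(oracle), tolerance = 1e-12)
})

test_that("distance matrices are symmetric with zero diagonal on random coils", {
    for (s in 1:3) {
        ens <- syntheticStructure(20, fold = "random_coil", seed = s)
        dm <- ensembleDistances(ens)
        expect_equal(dm, t(dm))
        expect_true(all(diag(dm) == 0))
        expect_true(all(dm >= 0))
    }
})

test_that("neighbour lookup uses a closed boundary and any-chain matching", {
    xyz <- cbind(seq(0, 12, by = 3), 0, 0)   # 3 A spacing
    dm <- ensembleDistances(pointEns(xyz))
    expect_equal(neighborsWithin("A:1", dm, 7.5), c("A:2", "A:3"))
    expect_equal(neighborsWithin("A:1", dm, 6), c("A:2", "A:3"))  # d = c kept
    expect_error(neighborsWithin("B:9", dm), "unknown residue")

    lone <- pointEns(rbind(c(0, 0, 0), c(100, 0, 0), c(103, 0, 0)))
    expect_length(neighborsWithin("A:1", ensembleDistances(lone), 7.5), 0)
})

test_that("the sigmoid kernel meets its boundary values exactly", {
    k <- sigmoidKernel(cutoff = 7.5, epsilon = 1e-3)
    expect_equal(phi(0, k), 1 - 1e-3)
    expect_equal(phi(7.5, k), 1e-3)
    expect_equal(phi(7.5 / 2, k), 0.5)
    expect_error(phi(-1, k), "non-negative")
    ## holds for other parameterizations too
    k2 <- sigmoidKernel(cutoff = 10, epsilon = 0.01)
    expect_equal(phi(c(0, 5, 10), k2), c(0.99, 0.5, 0.01))
})

test_that("phi is strictly decreasing", {
    k <- sigmoidKernel()
    set.seed(11)
    for (i in 1:200) {
        d <- sort(runif(2, 0, 20))
        expect_gt(phi(d[1], k), phi(d[2], k))
    }
})
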