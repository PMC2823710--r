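# two-chain toy complexes with controllable gap between the chains
complexEns <- function(gap, model = 1L) {
    makeEns(model = rep(model, 4),
            chain = c("A", "A", "B", "B"),
            resno = c(1L, 2L, 1L, 2L),
            elety = c("N", "CA", "CA", "CB"),
            elesy = c("N", "C", "C", "C"),
            x = c(0, 1.5, gap, gap + 1.5), y = 0, z = 0)
}

test_that("interface residues follow the 5 A backbone criterion", {
    far <- interfaceResidues(complexEns(100), "A", "B")
    expect_length(far$a, 0)
    expect_length(far$b, 0)

    near <- interfaceResidues(complexEns(4.9), "A", "B")
    expect_true("A:1" %in% near$a)      # backbone N at 4.9 A of B:1 CA
    expect_true("B:1" %in% near$b)

    out <- interfaceResidues(complexEns(5.1), "A", "B")
    expect_false("A:1" %in% out$a)

    boundary <- interfaceResidues(complexEns(5.0), "A", "B")
    expect_true("A:1" %in% boundary$a)  # within 5 A includes 5.0
})

test_that("hydrogens neither make contacts nor receive them", {
    ens <- makeEns(model = rep(1L, 3),
                   chain = c("A", "A", "B"),
                   resno = c(1L, 1L, 1L),
                   elety = c("CA", "H", "CA"),
                   elesy = c("C", "H", "C"),
                   x = c(0, 8, 12), y = 0, z = 0)
    ## B's CA is 4 A from A's hydrogen but 12 A from its backbone CA
    res <- interfaceResidues(ens, "A", "B")
    expect_length(res$a, 0)
    expect_length(res$b, 0)
})

test_that("side-chain proximity alone does not define an interface residue", {
    ## B:2 has only a CB side-chain atom near A, so B:2 is never interface,
    ## but its CB can still receive a contact from A's backbone
    ens <- complexEns(4.0)
    res <- interfaceResidues(ens, "A", "B")
    expect_false("B:2" %in% res$b)
})

test_that("a contact present in one model of an ensemble counts", {
    both <- new("StructureEnsemble",
        atoms = rbind(complexEns(100, 1L)@atoms, complexEns(4.5, 2L)@atoms),
        keys = complexEns(100)@keys)
    res <- interfaceResidues(both, "A", "B")
    expect_true("A:1" %in% res$a)
})

test_that("interface extraction is symmetric in the subunit labels", {
    ens <- complexEns(4.2)
    ab <- interfaceResidues(ens, "A", "B")
    ba <- interfaceResidues(ens, "B", "A")
    expect_equal(ab$a, ba$b)
    expect_equal(ab$b, ba$a)
    expect_error(interfaceResidues(ens, "A", "A"), "disjoint")
    expect_error(interfaceResidues(ens, "A", "Z"), "unknown chain")
})

test_that("Matthews correlation matches its integer oracle and conventions", {
    expect_equal(matthewsCC(confusionCounts(tp = 5, tn = 80, fp = 2, fn = 3)),
                 394 / sqrt(7 * 8 * 83 * 82), tolerance = 1e-12)
    expect_equal(matthewsCC(confusionCounts(10, 10, 10, 10)), 0)
    expect_equal(matthewsCC(confusionCounts(tp = 7, tn = 11)), 1)
    expect_warning(z <- matthewsCC(confusionCounts(tp = 5, fn = 2)),
                   "degenerate")
    expect_equal(z, 0)
})

test_that("MCC equals the binary correlation on random confusion tables", {
    set.seed(42)
    for (i in 1:1000) {
        n <- sample(1:30, 4, replace = TRUE)   # tp, fp, tn, fn all >= 1
        cc <- confusionCounts(n[1], n[2], n[3], n[4])
        truthVec <- c(rep(1, n[1]), rep(0, n[2]), rep(0, n[3]), rep(1, n[4]))
        predVec <- c(rep(1, n[1]), rep(1, n[2]), rep(0, n[3]), rep(0, n[4]))
        expect_equal(matthewsCC(cc), cor(truthVec, predVec),
                     tolerance = 1e-12)
    }
})

test_that("single-pass thresholding selects strict outliers", {
    d <- perResidueData(stats::setNames(c(rep(0, 9), 10), paste0("A:", 1:10)))
    expect_equal(thresholdSelection(d, 1), "A:10")   # mu 1, sigma 3
    flat <- perResidueData(stats::setNames(rep(1, 5), paste0("A:", 1:5)))
    expect_length(thresholdSelection(flat, 1), 0)
})

test_that("iterative thresholding rejects until stable", {
    d <- perResidueData(stats::setNames(c(rep(0, 8), 5, 10),
                                        paste0("A:", 1:10)))
    ## round 1: mu 1.5, sigma 3.2016, threshold 4.70 rejects 5 and 10;
    ## round 2: all zeros, no rejection
    expect_setequal_chr(iterativeThresholdSelection(d, 1),
                        c("A:9", "A:10"))
    flat <- perResidueData(stats::setNames(rep(1, 5), paste0("A:", 1:5)))
    expect_length(iterativeThresholdSelection(flat, 1), 0)
})

test_that("iterative selection contains the single-pass selection", {
    for (s in 1:25) {
        set.seed(s)
        v <- stats::setNames(abs(rnorm(30, 0.2, 0.3)), paste0("A:", 1:30))
        d <- perResidueData(v)
        for (ns in c(1, 2)) {
            a <- thresholdSelection(d, ns)
            b <- iterativeThresholdSelection(d, ns)
            expect_true(all(a %in% b))
            ## and 2 sigma selects a subset of 1 sigma
            expect_true(all(thresholdSelection(d, 2) %in%
                            thresholdSelection(d, 1)))
        }
    }
})

test_that("prediction scoring applies the ambiguous policy", {
    labels <- c("A:1" = "perturbed", "A:2" = "perturbed",
                "A:3" = "ambiguous", "A:4" = "unperturbed",
                "A:5" = "no-decision")
    cvAll <- new("ConfidenceVector",
        rho = stats::setNames(c(0.5, 0.5, 0, -0.5, NA), names(labels)),
        status = stats::setNames(c(rep("measured", 4), "excluded"),
                                 names(labels)))
    res <- new("ClassificationResult", labels = labels, rhoStart = cvAll,
               rhoFinal = cvAll, sigmaR = 1, guardTriggered = FALSE,
               calibration = NULL, iterations = 1L,
               data = perResidueData(stats::setNames(c(0.5, 0.6, 0.2, 0.1),
                                                     paste0("A:", 1:4)),
                                     missing = "A:5"))
    truth <- c("A:1", "A:3")
    neg <- scorePrediction(res, truth, "negative")
    expect_equal(c(neg@tp, neg@fp, neg@tn, neg@fn), c(1L, 1L, 1L, 1L))
    pos <- scorePrediction(res, truth, "positive")
    expect_equal(c(pos@tp, pos@fp, pos@tn, pos@fn), c(2L, 1L, 1L, 0L))
    drp <- scorePrediction(res, truth, "drop")
    expect_equal(c(drp@tp, drp@fp, drp@tn, drp@fn), c(1L, 1L, 1L, 0L))
    ## perfect prediction has no false counts
    perfect <- scoreSelection(truth, truth, paste0("A:", 1:5))
    expect_equal(c(perfect@fp, perfect@fn), c(0L, 0L))
    expect_error(scoreSelection("A:1", character(0), paste0("A:", 1:5)),
                 "empty")
})
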