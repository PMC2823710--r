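test_that("kFactor standardizes with the population convention", {
    expect_equal(kFactor(3, c(1, 2, 3, 4, 5))$k, 0)
    expect_equal(kFactor(5, c(1, 2, 3, 4, 5))$k, sqrt(2))
    deg <- kFactor(2, c(2, 2, 2))
    expect_true(deg$degenerate)
    expect_true(is.na(deg$k))
    expect_error(kFactor(1, numeric(0)), "non-empty")
})

test_that("calibration on nine zeros and a one is the enumerable fixed point", {
    ## every calibration subset is {0, 0, 1}: mu = 1/3, sigma = sqrt(2)/3
    d <- nineZerosOneOne()
    set.seed(1)
    cal <- calibrateExtremes(d, mappingParams())
    expect_equal(cal@kHigh, sqrt(2), tolerance = 1e-12)
    expect_equal(cal@kLow, -1 / sqrt(2), tolerance = 1e-12)
})

test_that("calibration is invariant under positive scaling of the data", {
    set.seed(5)
    v <- stats::setNames(abs(rnorm(40, 0.2, 0.2)), paste0("A:", 1:40))
    p <- mappingParams(calibMultiplier = 50)
    set.seed(9); c1 <- calibrateExtremes(perResidueData(v), p)
    set.seed(9); c2 <- calibrateExtremes(perResidueData(v * 10), p)
    expect_equal(c1@kHigh, c2@kHigh, tolerance = 1e-12)
    expect_equal(c1@kLow, c2@kLow, tolerance = 1e-12)
})

test_that("degenerate or undersized data cannot be calibrated", {
    flat <- perResidueData(stats::setNames(rep(0.3, 10), paste0("A:", 1:10)))
    expect_error(calibrateExtremes(flat, mappingParams()), "equal")
    tiny <- perResidueData(c("A:1" = 0, "A:2" = 1))
    expect_error(calibrateExtremes(tiny, mappingParams()), "at least 3")
})

test_that("the Gamma transform clips at the calibrated extremes", {
    cal <- new("Calibration", kHigh = 2, kLow = -1)
    expect_equal(gammaTransform(NA_real_, cal), 0)        # degenerate subset
    expect_equal(gammaTransform(2, cal), 1)
    expect_equal(gammaTransform(5, cal), 1)
    expect_equal(gammaTransform(-1, cal), -1)
    expect_equal(gammaTransform(-3, cal), -1)
    expect_equal(gammaTransform(1, cal), 0.5)             # k_high / 2
    expect_equal(gammaTransform(-0.5, cal), -0.5)
    expect_equal(gammaTransform(0, cal), 0)
})

test_that("identical data yield zero confidence everywhere", {
    ## every subset has zero spread, so every increment is 0
    flat <- perResidueData(stats::setNames(rep(0.3, 10), paste0("A:", 1:10)))
    cal <- new("Calibration", kHigh = 1, kLow = -1)
    set.seed(1)
    cv <- attributeConfidences(flat, cal, mappingParams())
    expect_equal(unname(confidences(cv)), rep(0, 10))
})

test_that("the unique maximum attains confidence 1 exactly", {
    ## every subset containing the 1 is {0, 0, 1}; its k equals kHigh
    d <- nineZerosOneOne()
    set.seed(1)
    cal <- calibrateExtremes(d, mappingParams())
    cv <- attributeConfidences(d, cal, mappingParams())
    expect_equal(unname(confidences(cv)["A:10"]), 1)
})

test_that("a zero residue matches the hypergeometric expectation -2/9", {
    ## subset of a zero residue: {0,0,0} (Gamma 0) unless the single 1 is
    ## drawn (prob 2/9), then k = kLow and Gamma = -1
    d <- nineZerosOneOne()
    set.seed(1)
    cal <- calibrateExtremes(d, mappingParams())
    cv <- attributeConfidences(d, cal, mappingParams())  # n_trial = 1000
    zeros <- confidences(cv)[paste0("A:", 1:9)]
    expect_lt(abs(mean(zeros) - (-2 / 9)), 0.02)
    expect_true(all(abs(zeros - (-2 / 9)) < 0.04))   # ~3 binomial SD each
})

test_that("confidences stay in [-1, 1] and extremes bracket the rest", {
    p <- mappingParams(calibMultiplier = 30, trialMultiplier = 30)
    for (s in 1:20) {
        set.seed(s)
        v <- stats::setNames(abs(rnorm(25, 0.3, 0.25)), paste0("A:", 1:25))
        d <- perResidueData(v)
        cal <- calibrateExtremes(d, p)
        rho <- confidences(attributeConfidences(d, cal, p))
        expect_true(all(rho >= -1 & rho <= 1))
        expect_equal(unname(which.max(rho)), unname(which.max(v)))
        expect_equal(unname(which.min(rho)), unname(which.min(v)))
    }
})

test_that("confidences are invariant under positive affine scaling", {
    set.seed(21)
    v <- stats::setNames(abs(rnorm(30, 0.3, 0.2)), paste0("A:", 1:30))
    d1 <- perResidueData(v)
    d2 <- perResidueData(v * 4 + 0.7)
    p <- mappingParams(calibMultiplier = 30, trialMultiplier = 30)
    run <- function(d) {
        set.seed(17)
        cal <- calibrateExtremes(d, p)
        confidences(attributeConfidences(d, cal, p))
    }
    expect_equal(run(d1), run(d2), tolerance = 1e-12)
})

test_that("a fixed seed reproduces the confidence vector bit for bit", {
    ens <- syntheticStructure(40)
    sim <- syntheticData(ens, patchRadius = 9, seed = 4)
    p <- mappingParams(seed = 4, calibMultiplier = 100, trialMultiplier = 50)
    r1 <- mapPerturbations(ens, sim$data, p)
    r2 <- mapPerturbations(ens, sim$data, p)
    expect_identical(confidences(r1), confidences(r2))
    expect_identical(residueLabels(r1), residueLabels(r2))
})
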