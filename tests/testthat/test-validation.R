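test_that("figures of merit match hand arithmetic", {
    expect_equal(rmse(c(1, 2), c(2, 1)), 1)
    expect_equal(rmse(1:5, 1:5), 0)
    expect_equal(rmse(c(3, 4), c(0, 0)), sqrt(25 / 2))
    expect_error(rmse(numeric(0), numeric(0)), "nonzero length")

    y <- c(1, 2, 3, 4)
    expect_equal(rSquared(y, y), 1)
    expect_equal(rSquared(y, rep(mean(y), 4)), 0)
    expect_lt(rSquared(y, rev(y)), 0)
    expect_error(rSquared(rep(2, 4), y), "constant")

    expect_equal(round(relativeRMSEP(1.8844, 100), 2), 1.88)
    expect_equal(round(relativeRMSEP(1.7812, 100), 2), 1.78)
    expect_equal(relativeRMSEP(0, 100), 0)
    expect_error(relativeRMSEP(1, 0), "range")
})

test_that("classification metrics follow their confusion-count definitions", {
    m <- classificationMetrics(TP = 9, TN = 8, FP = 2, FN = 1)
    expect_equal(unname(m), c(85, 90, 80))
    expect_equal(unname(classificationMetrics(5, 5, 0, 0)), c(100, 100, 100))
    expect_warning(m0 <- classificationMetrics(0, 10, 0, 0), "sensitivity undefined")
    expect_true(is.na(m0["sensitivity"]))
    expect_error(classificationMetrics(-1, 1, 1, 1), "non-negative")
})

test_that("LOO-CV recovers noiseless mixtures and is deterministic", {
    s0 <- noiselessStudy(seed = 23)
    cal <- splitByLabel(s0, "calibration")
    cv <- looCV(cal, fMax = 3, kind = "plsr")
    expect_lt(cv[1], 1e-6)
    expect_identical(cv, looCV(cal, fMax = 3, kind = "plsr"))
})

test_that("LOO-CV never beats the training fit (optimism inequality)", {
    for (seed in 1:3) {
        set.seed(seed)
        n <- 20; p <- 8
        X <- matrix(rnorm(n * p), n)
        y <- as.numeric(X %*% rnorm(p) + rnorm(n))
        cv <- looCV(X, y, kind = "plsr", fMax = 4)
        path <- garlicNIR:::plsPath(X, y, 4)
        rc <- vapply(1:4, function(f)
            rmse(y, X %*% path$beta[, f] + path$intercept[f]), numeric(1))
        expect_true(all(cv >= rc - 1e-10))
    }
})

test_that("LOO-CV refits scheme parameters inside each fold", {
    s <- simulateDataset(design = calibrationDesign(), seed = 31)
    cal <- spectra(s)[1:12, ]
    y <- sampleMeta(s)$fraction[1:12]
    sch <- preprocessScheme("msc", list(list(name = "msc", params = list())))
    cv_refit <- looCV(cal, y, kind = "plsr", fMax = 2, scheme = sch)
    # preprocessing the whole set once (leaky) gives a different curve
    leaky <- msc(cal, colMeans(cal))
    cv_leak <- looCV(leaky, y, kind = "plsr", fMax = 2)
    expect_false(isTRUE(all.equal(cv_refit, cv_leak)))
})

test_that("parsimonious complexity selection follows the tolerance rule", {
    curve <- c(5, 3, 2, 1.01, 1.0, 0.999)
    expect_equal(selectComplexity(curve, tolerance = 0.02), 4L)
    expect_equal(selectComplexity(rep(2, 6)), 1L)
    expect_equal(selectComplexity(curve, tolerance = 0), which.min(curve))
    expect_error(selectComplexity(numeric(0)), "empty")
})

test_that("Monte Carlo validation is reproducible and honors the protocol", {
    ds <- simulateSeparableClasses(seed = 41, replicates = 9L,
                                   nModelPerGroup = 30L)
    r1 <- monteCarloValidate(ds$model, ds$validation, f = 3, iterations = 25,
                             trainPerGroup = 20, seed = 7)
    r2 <- monteCarloValidate(ds$model, ds$validation, f = 3, iterations = 25,
                             trainPerGroup = 20, seed = 7)
    expect_identical(r1@mean, r2@mean)
    expect_identical(r1@sd, r2@sd)

    # separable classes: perfect external validation with zero spread
    expect_equal(unname(r1@mean["CCR", "validation"]), 100)
    expect_equal(unname(r1@sd["CCR", "validation"]), 0)

    # single iteration is flagged degenerate with zero SDs
    r3 <- monteCarloValidate(ds$model, ds$validation, f = 3, iterations = 1,
                             trainPerGroup = 20, seed = 7)
    expect_true(r3@degenerate)
    expect_true(all(r3@sd == 0))

    expect_error(monteCarloValidate(ds$model, ds$validation, f = 3,
                                    iterations = 2, trainPerGroup = 30),
                 "trainPerGroup")
})

test_that("CCR lies between sensitivity and specificity for balanced groups", {
    ds <- simulateDiscriminationStudy(seed = 43)
    r <- monteCarloValidate(ds$model, ds$validation, f = 5, iterations = 20,
                            seed = 3)
    for (set in colnames(r@mean)) {
        s <- r@mean["sensitivity", set]; p <- r@mean["specificity", set]
        expect_gte(r@mean["CCR", set], min(s, p) - 1e-9)
        expect_lte(r@mean["CCR", set], max(s, p) + 1e-9)
    }
})

test_that("the complexity curve finds the smallest sufficient model", {
    ds <- simulateSeparableClasses(seed = 47, replicates = 9L,
                                   nModelPerGroup = 30L)
    cc <- complexityCurve(ds$model, ds$validation, fRange = 1:4,
                          iterations = 15, trainPerGroup = 20, seed = 5)
    expect_equal(nrow(cc$curve), 4L)
    expect_true(cc$optimal %in% 1:4)
    # once the curve is at 100, the optimum is the first f reaching it
    at100 <- cc$curve$f[cc$curve$test_ccr >= 100 - 1e-9]
    if (length(at100)) expect_equal(cc$optimal, at100[1])
    cc1 <- complexityCurve(ds$model, ds$validation, fRange = 3,
                           iterations = 5, trainPerGroup = 20, seed = 5)
    expect_equal(cc1$optimal, 3)
})

test_that("MCReport renders as a table and as CSV", {
    ds <- simulateSeparableClasses(seed = 53, replicates = 9L,
                                   nModelPerGroup = 30L)
    r <- monteCarloValidate(ds$model, ds$validation, f = 2, iterations = 5,
                            trainPerGroup = 20, seed = 11)
    tab <- mcReportTable(r)
    expect_equal(tab$metric, c("CCR", "sensitivity", "specificity"))
    expect_true(all(c("training_mean", "test_sd", "validation_mean")
                    %in% colnames(tab)))
    f <- tempfile(fileext = ".csv")
    writeMCReport(r, f)
    expect_equal(utils::read.csv(f)$metric, tab$metric)
})
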