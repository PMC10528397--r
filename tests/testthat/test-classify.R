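test_that("PLS-DA separates well-separated classes and enforces two classes", {
    cls <- separableGaussianClasses()
    m <- fitPLSDA(cls$X, cls$labels, f = 2)
    pr <- predictPLSDA(m, cls$X)
    expect_equal(pr$label, cls$labels)

    expect_error(fitPLSDA(cls$X, rep("a", nrow(cls$X)), f = 2), "two classes")

    # class-mean spectra are classified correctly
    mu <- rbind(colMeans(cls$X[cls$labels == "a", ]),
                colMeans(cls$X[cls$labels == "b", ]))
    expect_equal(predictPLSDA(m, mu)$label, c("a", "b"))
})

test_that("swapping class codes flips every prediction", {
    cls <- separableGaussianClasses(sep = 2, seed = 9)
    m1 <- fitPLSDA(cls$X, cls$labels, f = 3)
    swapped <- ifelse(cls$labels == "a", "b2", "a2")  # reverses sort order
    m2 <- fitPLSDA(cls$X, swapped, f = 3)
    p1 <- predictPLSDA(m1, cls$X)
    p2 <- predictPLSDA(m2, cls$X)
    expect_equal(p2$score, -p1$score, tolerance = 1e-10)
    # identical partition, opposite codes
    expect_equal(p2$label == "b2", p1$label == "a")
})

test_that("a score exactly at the threshold is assigned to the +1 class", {
    cls <- separableGaussianClasses()
    m <- fitPLSDA(cls$X, cls$labels, f = 2)
    # synthesize a spectrum whose score is exactly the threshold
    beta <- coefVector(m@base)
    x0 <- matrix(0, 1, length(beta))
    x0[1] <- (m@threshold - modelIntercept(m@base)) / beta[1]
    pr <- predictPLSDA(m, x0)
    expect_equal(pr$score, m@threshold, tolerance = 1e-9)
    expect_equal(pr$label, m@classMap[["+1"]], ignore_attr = TRUE)
})

test_that("OC-PLS acceptance is nominal on its own training population", {
    # 200 replicate preparations of one fixed mixture: Gaussian variability,
    # the regime the F/Box threshold calibration assumes
    d <- designSpec(20, replicates = 200L, adulterant = "corn_flour",
                    setLabel = "model")
    s <- simulateDataset(design = d, seed = 5)
    oc <- fitOCPLS(s, f = 7, alpha = 0.05)
    acc <- mean(predictOCPLS(oc, s)$accepted)
    # 99% binomial interval around 1 - alpha at n = 200
    halfwidth <- qnorm(0.995) * sqrt(0.95 * 0.05 / 200)
    expect_gte(acc, 0.95 - halfwidth)
    expect_lte(acc, min(1, 0.95 + halfwidth))
})

test_that("the two OC-PLS rules reject their own failure modes", {
    d <- designSpec(c(15, 20, 25), replicates = 30L, adulterant = "corn_flour",
                    setLabel = "model")
    s <- simulateDataset(design = d, seed = 13)
    X <- spectra(s)
    oc <- fitOCPLS(X, f = 4, alpha = 0.05)

    # training mean spectrum is accepted
    expect_true(predictOCPLS(oc, matrix(colMeans(X), 1))$accepted)

    # gross shift along a loading direction -> rejected via d2
    t_sd <- oc@scoreSD[1]
    dir <- oc@loadings[, 1]
    far <- matrix(colMeans(X) + 100 * t_sd * dir / sqrt(sum(dir^2)), 1)
    v <- predictOCPLS(oc, far)
    expect_false(v$accepted)
    expect_gt(v$d2, oc@dCrit)

    # large perturbation orthogonal to all loadings -> rejected via q,
    # d2 essentially unchanged
    set.seed(1)
    r <- rnorm(ncol(X))
    P <- oc@loadings
    r <- r - P %*% solve(crossprod(P), crossprod(P, r))
    # also orthogonal to the projection directions so scores are untouched
    R <- oc@projection
    r <- r - R %*% solve(crossprod(R), crossprod(R, r))
    r <- 10 * r / sqrt(sum(r^2))
    base <- matrix(colMeans(X), 1)
    v0 <- predictOCPLS(oc, base)
    v1 <- predictOCPLS(oc, base + matrix(r, 1))
    expect_false(v1$accepted)
    expect_gt(v1$q, oc@qCrit)
    expect_equal(v1$d2, v0$d2, tolerance = 1e-6)

    # an all-zero spectrum is nowhere near the class
    expect_false(predictOCPLS(oc, matrix(0, 1, ncol(X)))$accepted)
})

test_that("the acceptance region is monotone in the thresholds", {
    d <- designSpec(c(10, 30), replicates = 20L, adulterant = "corn_starch",
                    setLabel = "model")
    s <- simulateDataset(garlicEndmember(), cornStarchEndmember(),
                         design = d, seed = 17)
    oc <- fitOCPLS(s, f = 3, alpha = 0.10)
    probe <- simulateDataset(garlicEndmember(), cornStarchEndmember(),
                             design = d, seed = 18)
    tight <- predictOCPLS(oc, probe)$accepted
    loose <- predictOCPLS(oc, probe, thresholdScale = 3)$accepted
    expect_true(all(loose[tight]))
})

test_that("overlapping classes can both accept the same sample (soft logic)", {
    d1 <- designSpec(c(20, 25), 20L, "corn_flour", "model")
    s1 <- simulateDataset(design = d1, seed = 19)
    # second model trained on nearly the same population
    s2 <- simulateDataset(design = d1, seed = 20)
    oc1 <- fitOCPLS(s1, f = 3)
    oc2 <- fitOCPLS(s2, f = 3)
    x <- matrix(colMeans(spectra(s1)), 1)
    expect_true(predictOCPLS(oc1, x)$accepted)
    expect_true(predictOCPLS(oc2, x)$accepted)
})

test_that("soft one-class rules are less specific than hard discrimination
           when the adulterants are spectrally similar", {
    nearStarch <- function() {
        b <- cornFlourEndmember()@bands
        b[, "amplitude"] <- b[, "amplitude"] * c(0.92, 1.08, 0.95, 1.05, 0.92)
        endmemberSpec("corn_starch", b, 0.22, 0.45)
    }
    lv <- c(20, 25, 30, 35, 50)
    oc_spec <- da_spec <- numeric(4)
    for (i in 1:4) {
        s1 <- simulateDataset(garlicEndmember(), cornFlourEndmember(),
                              designSpec(lv, 15L, "corn_flour", "model"),
                              seed = i)
        s2 <- simulateDataset(garlicEndmember(), nearStarch(),
                              designSpec(lv, 15L, "corn_starch", "model"),
                              seed = 1000 + i)
        both <- bindSamples(s1, s2)
        g <- sampleMeta(both)$adulterant
        oc <- fitOCPLS(spectra(s1), f = 7)
        oc_spec[i] <- 100 * mean(!predictOCPLS(oc, spectra(s2))$accepted)
        da <- fitPLSDA(both, f = 7)
        pr <- predictPLSDA(da, both)$label
        da_spec[i] <- 100 * mean(pr[g == "corn_starch"] == "corn_starch")
    }
    expect_lt(mean(oc_spec), mean(da_spec))
})
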