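test_that("snv centers and scales every spectrum", {
    expect_equal(snv(c(1, 2, 3)), c(-1, 0, 1))
    expect_equal(snv(c(-1, 0, 1)), c(-1, 0, 1))
    expect_error(snv(c(5, 5, 5)), "degenerate")

    X <- spectra(toySpectraSet(5))
    out <- snv(X)
    expect_lt(max(abs(rowMeans(out))), 1e-12)
    expect_lt(max(abs(apply(out, 1, sd) - 1)), 1e-12)
})

test_that("Savitzky-Golay filtering is exact on polynomials", {
    grid <- seq(1000, 1300, by = 2)
    # smoothing reproduces any polynomial of degree <= polyorder, edges included
    y <- 2 + 0.01 * grid + 3e-5 * grid^2
    expect_equal(sgFilter(y, 15, 2, 0, spacing = 2), y, tolerance = 1e-8)
    # first derivative of a quadratic matches the analytic derivative inside
    d1 <- sgFilter(y, 15, 2, 1, spacing = 2)
    interior <- 8:(length(grid) - 7)
    expect_equal(d1[interior], (0.01 + 6e-5 * grid)[interior], tolerance = 1e-8)
    # derivative of a constant is zero
    expect_equal(sgFilter(rep(1.5, 100), 15, 2, 1, spacing = 2), rep(0, 100))
    expect_error(sgFilter(y, 14, 2, 1), "odd")
    expect_error(sgFilter(y, 15, 2, 3), "polyorder")
    expect_error(sgFilter(y[1:10], 15, 2, 0), "window larger")
})

test_that("SG derivative agrees with central finite differences on smooth signals", {
    grid <- seq(1000, 1500, by = 2)
    y <- sin(grid / 50) + 0.3 * exp(-(grid - 1200)^2 / (2 * 40^2))
    d1 <- sgFilter(y, 15, 2, 1, spacing = 2)
    fd <- (y[3:length(y)] - y[1:(length(y) - 2)]) / 4
    interior <- 9:(length(y) - 8)
    expect_lt(max(abs(d1[interior] - fd[interior - 1])), 5e-4)
})

test_that("MSC inverts affine distortion and is idempotent", {
    ref <- toyReference()
    expect_equal(msc(ref, ref), ref)
    expect_equal(msc(3 + 2 * ref, ref), ref)

    set.seed(4)
    X <- spectra(toySpectraSet(6))
    once <- msc(X, ref)
    expect_equal(msc(once, ref), once, tolerance = 1e-10)
    expect_error(msc(rep(1, length(ref)) + rnorm(length(ref), 0, 1e-15), ref),
                 "degenerate")
})

test_that("EMSC removes polynomial baselines exactly and beats MSC under drift", {
    grid <- toyGrid()
    ref <- toyReference(grid)
    t <- (grid - min(grid)) / (max(grid) - min(grid))
    expect_equal(emsc(ref, ref, wl = grid), ref, tolerance = 1e-10)
    expect_equal(emsc(2 * ref + 0.5 * t^2, ref, wl = grid), ref,
                 tolerance = 1e-10)
    # drift-distorted spectra: EMSC residual to truth <= MSC residual
    nm <- noiseModel(0.05, 0.02, 0.05, 0, 0)
    s <- simulateDataset(design = calibrationDesign(), noise = nm, seed = 3)
    s0 <- simulateDataset(design = calibrationDesign(), noise = zeroNoiseModel(),
                          seed = 3)
    g <- defaultGrid()
    refm <- colMeans(spectra(s0))
    err <- function(M) sqrt(mean((M - spectra(msc(s0, refm)))^2))
    e_msc <- err(spectra(msc(s, refm)))
    e_emsc <- err(spectra(emsc(s, refm)))
    expect_lte(e_emsc, e_msc)
})

test_that("ISC matches MSC on exact affine distortions and is idempotent", {
    ref <- toyReference()
    expect_equal(isc(ref, ref), ref)
    expect_equal(isc((ref - 3) / 2, ref), ref, tolerance = 1e-10)

    set.seed(8)
    X <- t(vapply(1:5, function(i) rnorm(1, 0, 0.5) + exp(rnorm(1, 0, 0.3)) * ref,
                  numeric(length(ref))))
    expect_equal(isc(X, ref), msc(X, ref), tolerance = 1e-8)
    once <- isc(spectra(toySpectraSet(4)), ref)
    expect_equal(isc(once, ref), once, tolerance = 1e-10)
})

test_that("EISC corrects by the inverse extended fit", {
    grid <- toyGrid()
    ref <- toyReference(grid)
    t <- (grid - min(grid)) / (max(grid) - min(grid))
    expect_equal(eisc(ref, ref, wl = grid), ref, tolerance = 1e-10)
    # x carries gain + quadratic baseline; the inverse fit recovers ref
    x <- 2 * ref + 0.5 * t^2 + 0.1
    expect_equal(eisc(x, ref, wl = grid), ref, tolerance = 1e-10)
    once <- eisc(spectra(toySpectraSet(4, grid)), ref, wl = grid)
    expect_equal(eisc(once, ref, wl = grid), once, tolerance = 1e-8)
})

test_that("detrend removes polynomial trends and is an orthogonal projection", {
    grid <- toyGrid()
    t <- (grid - min(grid)) / (max(grid) - min(grid))
    quad <- 1 + 2 * t - 3 * t^2
    expect_lt(max(abs(detrendSpectra(quad, wl = grid))), 1e-10)
    X <- spectra(toySpectraSet(5, grid))
    out <- detrendSpectra(X, wl = grid)
    expect_lt(max(abs(rowMeans(out))), 1e-12)
    expect_equal(detrendSpectra(out, wl = grid), out, tolerance = 1e-10)
})

test_that("unit-variance scaling uses training column SDs only", {
    set.seed(10)
    sch <- preprocessScheme("uv", list(list(name = "unit_variance", params = list())))
    Xtr <- matrix(rnorm(200, sd = 2), 20)
    Xval <- matrix(rnorm(100, sd = 5), 10)
    r <- fitApplyScheme(sch, Xtr, others = list(Xval))
    expect_equal(apply(r$train, 2, sd), rep(1, 10), tolerance = 1e-12)
    # validation columns scaled by training SDs, not their own
    expect_equal(r$others[[1]], sweep(Xval, 2, apply(Xtr, 2, sd), "/"))
    Xconst <- cbind(Xtr[, 1:9], 1)
    expect_error(fitScheme(sch, Xconst), "zero-variance")
})

test_that("the default catalogue holds exactly 56 distinct schemes in stable order", {
    cat56 <- buildCatalogue()
    expect_length(cat56, 56L)
    ids <- vapply(cat56, schemeId, character(1))
    expect_false(anyDuplicated(ids) > 0)
    expect_identical(ids, vapply(buildCatalogue(), schemeId, character(1)))
    expect_true("none" %in% ids)
    # restricted configuration
    small <- buildCatalogue(scatter = c("none", "snv"), sg = "none",
                            unitVariance = FALSE)
    expect_length(small, 2L)
})

test_that("scheme fitting learns on training rows only and composes steps", {
    s <- toySpectraSet(8)
    idn <- preprocessScheme("none", list())
    expect_equal(spectra(fitScheme(idn, s)$train), spectra(s))

    comp <- preprocessScheme("snv+d1", list(
        list(name = "snv", params = list()),
        list(name = "sg_derivative",
             params = list(window = 15, polyorder = 2, derivOrder = 1))))
    direct <- sgFilter(snv(spectra(s)), 15, 2, 1, spacing = diff(toyGrid())[1])
    expect_equal(spectra(fitScheme(comp, s)$train), direct, ignore_attr = TRUE)

    msch <- preprocessScheme("msc", list(list(name = "msc", params = list())))
    fit <- fitScheme(msch, s)
    expect_equal(fit$fitted@learned[[1]]$reference, colMeans(spectra(s)))

    # permuting non-training rows cannot change the learned parameters
    other <- toySpectraSet(5, seed = 99)
    perm <- other[, c(3, 1, 5, 2, 4)]
    a <- applyScheme(fit$fitted, other)
    b <- applyScheme(fit$fitted, perm)
    expect_equal(spectra(a)[c(3, 1, 5, 2, 4), ], unname(spectra(b)),
                 ignore_attr = TRUE)
})

test_that("MSC and ISC restore scatter-distorted mixtures to the clean truth", {
    nm <- noiseModel(scatterGainSD = 0.1, scatterOffsetSD = 0.05,
                     driftSD = 0, noiseSD = 0, replicateSD = 0)
    s <- simulateDataset(design = calibrationDesign(), noise = nm, seed = 21)
    s0 <- simulateDataset(design = calibrationDesign(), noise = zeroNoiseModel(),
                          seed = 21)
    ref <- colMeans(spectra(s0))
    # each correction maps the distorted spectra onto the same representative
    # it assigns the clean mixtures (the shared reference fixes the frame)
    expect_equal(spectra(msc(s, ref)), spectra(msc(s0, ref)), tolerance = 1e-8)
    expect_equal(spectra(isc(s, ref)), spectra(isc(s0, ref)), tolerance = 1e-8)
})
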