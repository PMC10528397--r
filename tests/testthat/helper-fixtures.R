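# Small in-code fixtures shared across test files.

# Tiny uniform grid for fast tests.
toyGrid <- function(n = 60, from = 1000, by = 10) seq(from, by = by, length.out = n)

# A SpectraSet with smooth random spectra (sum of a few random Gaussians).
toySpectraSet <- function(n = 6, grid = toyGrid(), seed = 42, meta = NULL) {
    set.seed(seed)
    X <- t(vapply(seq_len(n), function(i) {
        centers <- runif(3, min(grid), max(grid))
        amps <- runif(3, 0.1, 0.5)
        w <- runif(3, 30, 80)
        rowSums(vapply(1:3, function(j)
            amps[j] * exp(-(grid - centers[j])^2 / (2 * w[j]^2)),
            numeric(length(grid)))) + 0.2 + 0.3 * seq_along(grid) / length(grid)
    }, numeric(length(grid))))
    SpectraSet(X, grid, meta)
}

# Random smooth reference spectrum on a grid.
toyReference <- function(grid = toyGrid(), seed = 1) {
    set.seed(seed)
    0.3 + 0.4 * (grid - min(grid)) / (max(grid) - min(grid)) +
        0.5 * exp(-(grid - mean(grid))^2 / (2 * 100^2))
}

# Noiseless calibration + validation study (exact rank-1 mixtures).
noiselessStudy <- function(adulterant = "corn_flour", seed = 1) {
    simulateCalibrationStudy(adulterant, noise = zeroNoiseModel(), seed = seed)
}

# Two well-separated Gaussian classes in a modest-dimension space.
separableGaussianClasses <- function(nPerClass = 20, p = 25, sep = 10, seed = 3) {
    set.seed(seed)
    dir <- rnorm(p); dir <- dir / sqrt(sum(dir^2))
    X1 <- matrix(rnorm(nPerClass * p), nPerClass)
    X2 <- matrix(rnorm(nPerClass * p), nPerClass) +
        matrix(sep * dir, nPerClass, p, byrow = TRUE)
    list(X = rbind(X1, X2),
         labels = rep(c("a", "b"), each = nPerClass))
}
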