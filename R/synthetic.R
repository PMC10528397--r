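#' @include AllClasses.R SpectraSet.R utils.R
NULL

#' Default wavelength grid
#'
#' 1000-2500 nm at 2 nm spacing (751 points). The instrument range is
#' 10,000-4000 cm^-1; a uniform nanometre grid is used because the
#' Savitzky-Golay filters assume uniform spacing.
#'
#' @return Numeric vector of wavelengths in nm.
#' @export
defaultGrid <- function() seq(1000, 2500, by = 2)

#' Endmember specifications for the pure powders
#'
#' Parametric stand-ins for the pure-component FT-NIR spectra, synthetic by
#' construction: Gaussian bands at the characteristic overtone/combination
#' band centers of each powder on a rising linear baseline. Garlic carries
#' bands near 1160, 1450, 1725, 1930, 2100, 2235 and 2325 nm; corn flour near
#' 1445, 1725, 1930, 2100 and 2280 nm; corn starch shares the carbohydrate
#' bands (1445, 1930, 2225 nm) but with distinct amplitudes and a
#' systematically lower absorbance level above 1400 nm. Amplitudes and widths
#' are illustrative defaults, not fits to any measured spectrum.
#'
#' @param name component name.
#' @param bands numeric matrix with columns `center`, `width`, `amplitude`.
#' @param baselineOffset,baselineSlope linear baseline parameters (AU; slope
#'   per unit of normalized wavelength).
#' @return An [EndmemberSpec-class].
#' @export
endmemberSpec <- function(name, bands, baselineOffset = 0, baselineSlope = 0) {
    if (!is.matrix(bands)) bands <- matrix(bands, ncol = 3, byrow = TRUE)
    colnames(bands) <- c("center", "width", "amplitude")
    new("EndmemberSpec", name = name, bands = bands,
        baselineOffset = baselineOffset, baselineSlope = baselineSlope)
}

#' @rdname endmemberSpec
#' @export
garlicEndmember <- function() {
    endmemberSpec("garlic", c(
        1160, 45, 0.10,
        1450, 50, 0.35,
        1725, 40, 0.15,
        1930, 55, 0.45,
        2100, 50, 0.30,
        2235, 40, 0.22,
        2325, 35, 0.18),
        baselineOffset = 0.25, baselineSlope = 0.50)
}

#' @rdname endmemberSpec
#' @export
cornFlourEndmember <- function() {
    endmemberSpec("corn_flour", c(
        1445, 48, 0.30,
        1725, 40, 0.12,
        1930, 55, 0.40,
        2100, 50, 0.28,
        2280, 40, 0.16),
        baselineOffset = 0.22, baselineSlope = 0.45)
}

#' @rdname endmemberSpec
#' @export
cornStarchEndmember <- function() {
    endmemberSpec("corn_starch", c(
        1445, 48, 0.24,
        1930, 55, 0.30,
        2225, 45, 0.10),
        baselineOffset = 0.20, baselineSlope = 0.28)
}

#' Default measurement noise model
#'
#' Default variability levels of the simulated measurements: 5 % log-normal
#' multiplicative scatter gain, 0.02 AU additive offset, 0.005 AU linear
#' drift, 2e-4 AU per-channel noise (consistent with averaged FT-NIR scans)
#' and 1 % relative replicate perturbation of band amplitudes.
#'
#' @param scatterGainSD,scatterOffsetSD,driftSD,noiseSD,replicateSD see
#'   [NoiseModel-class].
#' @return A [NoiseModel-class].
#' @export
noiseModel <- function(scatterGainSD = 0.05, scatterOffsetSD = 0.02,
                       driftSD = 0.005, noiseSD = 2e-4, replicateSD = 0.01) {
    new("NoiseModel", scatterGainSD = scatterGainSD,
        scatterOffsetSD = scatterOffsetSD, driftSD = driftSD,
        noiseSD = noiseSD, replicateSD = replicateSD)
}

#' @rdname noiseModel
#' @export
defaultNoiseModel <- function() noiseModel()

#' @rdname noiseModel
#' @export
zeroNoiseModel <- function() noiseModel(0, 0, 0, 0, 0)

#' Concentration designs of the mixture study
#'
#' The study covers 26 adulterant mass-fraction levels in triplicate. The
#' calibration set spans 15 levels (0, 0.5, 1, 2, 3, 5, 10, 15, 20, 25, 30,
#' 35, 50, 70, 100 % w/w; 45 samples) and the validation set the 11
#' interleaved levels (2.5, 4, 7.5, 9.5, 11.5, 13.5, 17.5, 22.5, 27.5, 32.5,
#' 60 % w/w; 33 samples).
#'
#' @return Numeric vector of levels (% w/w).
#' @export
calibrationLevels <- function() {
    c(0, 0.5, 1, 2, 3, 5, 10, 15, 20, 25, 30, 35, 50, 70, 100)
}

#' @rdname calibrationLevels
#' @export
validationLevels <- function() {
    c(2.5, 4, 7.5, 9.5, 11.5, 13.5, 17.5, 22.5, 27.5, 32.5, 60)
}

#' @rdname calibrationLevels
#' @export
allLevels <- function() sort(c(calibrationLevels(), validationLevels()))

#' Build a DesignSpec
#'
#' @param levels adulterant fractions in % w/w.
#' @param replicates replicate preparations per level.
#' @param adulterant adulterant label.
#' @param setLabel set membership label for all samples in this design.
#' @return A [DesignSpec-class].
#' @export
designSpec <- function(levels, replicates = 3L, adulterant = "corn_flour",
                       setLabel = "calibration") {
    new("DesignSpec", levels = as.numeric(levels),
        replicates = as.integer(replicates), adulterant = adulterant,
        setLabel = setLabel)
}

#' @rdname designSpec
#' @export
calibrationDesign <- function(adulterant = "corn_flour") {
    designSpec(calibrationLevels(), 3L, adulterant, "calibration")
}

#' @rdname designSpec
#' @export
validationDesign <- function(adulterant = "corn_flour") {
    designSpec(validationLevels(), 3L, adulterant, "validation")
}

#' Evaluate an endmember spectrum on a wavelength grid
#'
#' Sum of Gaussian bands plus a linear baseline in normalized wavelength:
#' `sum_j A_j exp(-(lambda - c_j)^2 / (2 w_j^2)) + b0 + b1 * lambda_norm`.
#'
#' @param spec an [EndmemberSpec-class].
#' @param grid wavelength grid (nm).
#' @param amplitudes optional replacement band amplitudes (used internally
#'   for replicate perturbation).
#' @return Numeric absorbance vector, one value per grid point.
#' @export
makeEndmember <- function(spec, grid = defaultGrid(), amplitudes = NULL) {
    stopifnot(is(spec, "EndmemberSpec"))
    lam_norm <- if (length(grid) > 1)
        (grid - min(grid)) / (max(grid) - min(grid)) else rep(0, length(grid))
    out <- spec@baselineOffset + spec@baselineSlope * lam_norm
    b <- spec@bands
    amp <- if (is.null(amplitudes)) b[, "amplitude"] else amplitudes
    for (j in seq_len(nrow(b)))
        out <- out + amp[j] * exp(-(grid - b[j, "center"])^2 / (2 * b[j, "width"]^2))
    out
}

#' Linearly mix two endmember spectra
#'
#' `(1 - fraction/100) * e1 + (fraction/100) * e2`, the Beer-Lambert-style
#' linear mixing assumed by the calibration models.
#'
#' @param e1,e2 absorbance vectors of equal length (base component and
#'   adulterant).
#' @param fraction adulterant mass fraction in % w/w.
#' @return Mixed absorbance vector.
#' @export
mixSpectra <- function(e1, e2, fraction) {
    if (length(e1) != length(e2)) stop("endmember length mismatch")
    if (fraction < 0 || fraction > 100) stop("fraction must lie in [0, 100]")
    w <- fraction / 100
    (1 - w) * e1 + w * e2
}

#' Apply measurement effects to a clean spectrum
#'
#' Draws one multiplicative gain `b = exp(N(0, scatterGainSD^2))`, one
#' additive offset `a`, one linear drift coefficient `d` and i.i.d. channel
#' noise, and returns `a + b*x + d*lambda_norm + eps`. Uses the current RNG
#' state; seed externally (or via [simulateDataset()]) for reproducibility.
#'
#' @param x clean absorbance vector.
#' @param noise a [NoiseModel-class].
#' @param lam_norm normalized wavelength vector (computed from `grid` if
#'   omitted).
#' @param grid wavelength grid, used only to compute `lam_norm`.
#' @return Distorted absorbance vector.
#' @export
applyEffects <- function(x, noise = defaultNoiseModel(), lam_norm = NULL,
                         grid = NULL) {
    stopifnot(is(noise, "NoiseModel"))
    p <- length(x)
    if (is.null(lam_norm)) {
        if (is.null(grid)) grid <- seq_along(x)
        lam_norm <- if (p > 1) (grid - min(grid)) / (max(grid) - min(grid)) else 0
    }
    b <- exp(stats::rnorm(1, 0, noise@scatterGainSD))
    a <- stats::rnorm(1, 0, noise@scatterOffsetSD)
    d <- stats::rnorm(1, 0, noise@driftSD)
    eps <- if (noise@noiseSD > 0) stats::rnorm(p, 0, noise@noiseSD) else 0
    a + b * x + d * lam_norm + eps
}

#' Expand a DesignSpec into per-sample metadata
#'
#' One row per (level, replicate) in level-major order, with deterministic
#' sample identifiers.
#'
#' @param design a [DesignSpec-class].
#' @return `data.frame` with columns `sample_id`, `adulterant`, `fraction`,
#'   `replicate`, `set_label`.
#' @export
generateDesign <- function(design) {
    stopifnot(is(design, "DesignSpec"))
    lv <- rep(design@levels, each = design@replicates)
    rp <- rep(seq_len(design@replicates), times = length(design@levels))
    data.frame(
        sample_id = sprintf("%s_%s_%06.2f_r%d", design@adulterant,
                            substr(design@setLabel, 1, 3), lv, rp),
        adulterant = design@adulterant,
        fraction = lv,
        replicate = rp,
        set_label = design@setLabel,
        stringsAsFactors = FALSE)
}

#' Simulate a mixture-spectra dataset
#'
#' For every design entry: perturb the band amplitudes of both endmembers
#' with relative Gaussian noise (SD = `replicateSD`, shared per replicate
#' preparation), mix linearly by the adulterant fraction, and apply
#' multiplicative scatter, offset, drift and channel noise. Each sample uses
#' a seed substream derived from `seed` and its design index, so the
#' simulation is a pure function of its arguments and adding samples never
#' perturbs earlier draws.
#'
#' @param base endmember of the base material (default garlic).
#' @param adulterant endmember of the adulterant.
#' @param design one [DesignSpec-class] or a list of several (rows are
#'   concatenated in order).
#' @param noise a [NoiseModel-class].
#' @param grid wavelength grid (nm).
#' @param seed integer master seed.
#' @return A [SpectraSet-class] with one spectrum per design entry.
#' @export
simulateDataset <- function(base = garlicEndmember(),
                            adulterant = cornFlourEndmember(),
                            design = calibrationDesign(),
                            noise = defaultNoiseModel(),
                            grid = defaultGrid(), seed = 1) {
    if (is(design, "DesignSpec")) design <- list(design)
    meta <- do.call(rbind, lapply(design, generateDesign))
    p <- length(grid)
    lam_norm <- if (p > 1) (grid - min(grid)) / (max(grid) - min(grid)) else 0
    X <- matrix(0, nrow(meta), p)
    for (i in seq_len(nrow(meta))) {
        X[i, ] <- withSeed(substreamSeed(seed, i), {
            a1 <- base@bands[, "amplitude"]
            a2 <- adulterant@bands[, "amplitude"]
            if (noise@replicateSD > 0) {
                a1 <- a1 * (1 + stats::rnorm(length(a1), 0, noise@replicateSD))
                a2 <- a2 * (1 + stats::rnorm(length(a2), 0, noise@replicateSD))
            }
            e1 <- makeEndmember(base, grid, amplitudes = pmax(a1, 0))
            e2 <- makeEndmember(adulterant, grid, amplitudes = pmax(a2, 0))
            mixed <- mixSpectra(e1, e2, meta$fraction[i])
            applyEffects(mixed, noise, lam_norm = lam_norm)
        })
    }
    SpectraSet(X, grid, meta)
}

#' Simulate the full calibration study for one adulterant
#'
#' Calibration (45 samples, 15 levels x 3) plus validation (33 samples,
#' 11 levels x 3) sets in one [SpectraSet-class].
#'
#' @param adulterant `"corn_flour"` or `"corn_starch"`.
#' @param noise a [NoiseModel-class].
#' @param grid wavelength grid.
#' @param seed integer master seed.
#' @return A [SpectraSet-class] with `set_label` `calibration`/`validation`.
#' @export
simulateCalibrationStudy <- function(adulterant = c("corn_flour", "corn_starch"),
                                     noise = defaultNoiseModel(),
                                     grid = defaultGrid(), seed = 1) {
    adulterant <- match.arg(adulterant)
    em <- if (adulterant == "corn_flour") cornFlourEndmember() else cornStarchEndmember()
    simulateDataset(garlicEndmember(), em,
                    list(calibrationDesign(adulterant), validationDesign(adulterant)),
                    noise, grid, seed)
}

#' Simulate the two-adulterant discrimination study
#'
#' One group of garlic samples adulterated with corn flour, one with corn
#' starch; each group covers the 25 nonzero concentration levels in
#' triplicate (75 samples), randomly split without replacement into a model
#' set (50 per group) and an external validation set (25 per group),
#' stratified by group.
#'
#' @param noise a [NoiseModel-class].
#' @param grid wavelength grid.
#' @param seed integer master seed.
#' @param nModelPerGroup model-set size per group.
#' @return List with `SpectraSet` elements `model` and `validation`.
#' @export
simulateDiscriminationStudy <- function(noise = defaultNoiseModel(),
                                        grid = defaultGrid(), seed = 1,
                                        nModelPerGroup = 50L) {
    lv <- setdiff(allLevels(), 0)
    sets <- lapply(c("corn_flour", "corn_starch"), function(ad) {
        ds <- designSpec(lv, 3L, ad, "model")
        simulateDataset(garlicEndmember(),
                        if (ad == "corn_flour") cornFlourEndmember() else cornStarchEndmember(),
                        ds, noise, grid,
                        seed = substreamSeed(seed, if (ad == "corn_flour") 1001 else 2002))
    })
    picks <- withSeed(substreamSeed(seed, 3003), lapply(sets, function(s)
        sort(sample(nSamples(s), nModelPerGroup))))
    model_list <- validation_list <- list()
    for (g in 1:2) {
        s <- sets[[g]]
        idx <- picks[[g]]
        m <- s[, idx]
        v <- s[, setdiff(seq_len(nSamples(s)), idx)]
        SummarizedExperiment::colData(v)$set_label <- "external"
        model_list[[g]] <- m
        validation_list[[g]] <- v
    }
    list(model = bindSamples(model_list[[1]], model_list[[2]]),
         validation = bindSamples(validation_list[[1]], validation_list[[2]]))
}

#' Simulate a separable two-class discrimination scenario
#'
#' Flour- and starch-adulterated mixtures restricted to moderate doping
#' levels, where the between-class spectral difference (the doping fraction
#' times the flour/starch endmember difference) is an order of magnitude
#' larger than the within-class variability, so the classes are separable by
#' construction. This is the controlled scenario for verifying the Monte
#' Carlo discrimination protocol; the full concentration design, whose
#' sub-percent doping levels carry almost no class information relative to
#' replicate noise, is deliberately not separable (see the methods
#' vignette).
#'
#' @param noise a [NoiseModel-class].
#' @param grid wavelength grid.
#' @param seed integer master seed.
#' @param levels doping levels (% w/w) shared by both groups.
#' @param replicates replicates per level (`levels x replicates` samples per
#'   group).
#' @param nModelPerGroup model-set size per group (remainder is external
#'   validation).
#' @return List with `SpectraSet` elements `model` and `validation`.
#' @export
simulateSeparableClasses <- function(noise = defaultNoiseModel(),
                                     grid = defaultGrid(), seed = 1,
                                     levels = c(20, 25, 30, 35, 50),
                                     replicates = 15L,
                                     nModelPerGroup = 50L) {
    sets <- lapply(c("corn_flour", "corn_starch"), function(ad) {
        ds <- designSpec(levels, as.integer(replicates), ad, "model")
        simulateDataset(garlicEndmember(),
                        if (ad == "corn_flour") cornFlourEndmember() else cornStarchEndmember(),
                        ds, noise, grid,
                        seed = substreamSeed(seed, if (ad == "corn_flour") 7001 else 8002))
    })
    picks <- withSeed(substreamSeed(seed, 9003), lapply(sets, function(s)
        sort(sample(nSamples(s), nModelPerGroup))))
    model_list <- validation_list <- list()
    for (g in 1:2) {
        s <- sets[[g]]
        idx <- picks[[g]]
        v <- s[, setdiff(seq_len(nSamples(s)), idx)]
        SummarizedExperiment::colData(v)$set_label <- "external"
        model_list[[g]] <- s[, idx]
        validation_list[[g]] <- v
    }
    list(model = bindSamples(model_list[[1]], model_list[[2]]),
         validation = bindSamples(validation_list[[1]], validation_list[[2]]))
}
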