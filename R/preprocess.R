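#' @include AllClasses.R utils.R
#' @importFrom signal sgolayfilt
NULL

# Normalized-wavelength polynomial design matrix [1, t, t^2, ...].
polyBasis <- function(wl, degree) {
    t <- if (length(wl) > 1) (wl - min(wl)) / (max(wl) - min(wl)) else 0
    outer(t, 0:degree, `^`)
}

#' Standard normal variate transform
#'
#' Centers and scales each spectrum to zero mean and unit standard deviation
#' (n-1 denominator), removing per-spectrum offset and multiplicative scatter.
#'
#' @param x a spectrum (numeric vector), a samples-by-wavelengths matrix, or
#'   a [SpectraSet-class].
#' @return Object of the same type with transformed spectra.
#' @export
snv <- function(x) {
    M <- asSpectraMatrix(x)
    mu <- rowMeans(M)
    sd <- sqrt(rowSums(sweep(M, 1, mu)^2) / (ncol(M) - 1))
    if (any(sd <= 0))
        stop("degenerate input: constant spectrum has zero variance")
    out <- sweep(sweep(M, 1, mu), 1, sd, "/")
    res <- replaceSpectra(x, out)
    if (is.numeric(x) && !is.matrix(x)) drop(res) else res
}

#' Savitzky-Golay smoothing and derivatives
#'
#' Local least-squares polynomial filtering with boundary polynomial fits at
#' the edges (output length equals input length). Derivatives are scaled by
#' `spacing^derivOrder`, so a first derivative is in AU/nm on a nm grid.
#'
#' @param x spectrum vector, samples-by-wavelengths matrix, or
#'   [SpectraSet-class].
#' @param window odd filter window length (sampling points).
#' @param polyorder polynomial degree (`window > polyorder >= derivOrder`).
#' @param derivOrder derivative order (0 = smoothing).
#' @param spacing grid spacing in nm; taken from the `SpectraSet` grid when
#'   available.
#' @return Same type as `x`, filtered.
#' @export
sgFilter <- function(x, window = 15, polyorder = 2, derivOrder = 0,
                     spacing = NULL) {
    if (window %% 2 != 1) stop("window must be odd")
    if (!(window > polyorder && polyorder >= derivOrder))
        stop("need window > polyorder >= derivOrder")
    if (is(x, "SpectraSet")) {
        wl <- wavelengths(x)
        if (!isUniform(wl)) stop("Savitzky-Golay requires a uniform grid")
        if (is.null(spacing)) spacing <- diff(wl)[1]
    }
    if (is.null(spacing)) spacing <- 1
    M <- asSpectraMatrix(x)
    if (window > ncol(M)) stop("window larger than spectrum")
    out <- t(apply(M, 1, function(row)
        signal::sgolayfilt(row, p = polyorder, n = window, m = derivOrder,
                           ts = spacing)))
    res <- replaceSpectra(x, out)
    if (is.numeric(x) && !is.matrix(x)) drop(res) else res
}

# Row-wise forward regression x ~ a + b * reference (+ polynomial terms).
# Returns list(coef = rows x k matrix). Shared QR across rows.
.forwardFit <- function(M, D) {
    qrD <- qr(D)
    if (qrD$rank < ncol(D))
        stop("rank-deficient design (reference collinear with polynomial terms)")
    coef <- t(qr.coef(qrD, t(M)))
    coef
}

#' Multiplicative scatter correction
#'
#' Each spectrum is regressed on the reference over wavelengths,
#' `x ~ a + b * reference`; the corrected spectrum is `(x - a) / b`. In
#' scheme fitting the reference is the mean calibration spectrum.
#'
#' @param x spectra (vector, matrix or [SpectraSet-class]).
#' @param reference reference spectrum; defaults to the mean of `x`'s rows.
#' @return Same type as `x`, corrected.
#' @export
msc <- function(x, reference = NULL) {
    M <- asSpectraMatrix(x)
    if (is.null(reference)) reference <- colMeans(M)
    if (stats::var(reference) <= 0) stop("reference variance must be > 0")
    coef <- .forwardFit(M, cbind(1, reference))
    if (any(abs(coef[, 2]) < 1e-12)) stop("degenerate MSC fit: |b| < 1e-12")
    out <- sweep(M, 1, coef[, 1]) / coef[, 2]
    res <- replaceSpectra(x, out)
    if (is.numeric(x) && !is.matrix(x)) drop(res) else res
}

#' Extended multiplicative scatter correction
#'
#' Fits `x ~ a + b * reference + sum_k c_k * t^k` (t = normalized
#' wavelength) and corrects by `(x - a - sum_k c_k t^k) / b`, removing
#' wavelength-dependent baseline drift in addition to offset and gain.
#'
#' @inheritParams msc
#' @param wl wavelength grid for the polynomial terms (required for plain
#'   matrices; taken from a `SpectraSet` automatically).
#' @param degree polynomial degree of the baseline terms.
#' @return Same type as `x`, corrected.
#' @export
emsc <- function(x, reference = NULL, wl = NULL, degree = 2) {
    M <- asSpectraMatrix(x)
    if (is.null(wl)) wl <- if (is(x, "SpectraSet")) wavelengths(x) else seq_len(ncol(M))
    if (is.null(reference)) reference <- colMeans(M)
    D <- cbind(polyBasis(wl, degree), reference)
    coef <- .forwardFit(M, D)
    b <- coef[, ncol(D)]
    if (any(abs(b) < 1e-12)) stop("degenerate EMSC fit: |b| < 1e-12")
    baseline <- D[, -ncol(D), drop = FALSE] %*% t(coef[, -ncol(D), drop = FALSE])
    out <- (M - t(baseline)) / b
    res <- replaceSpectra(x, out)
    if (is.numeric(x) && !is.matrix(x)) drop(res) else res
}

#' Inverse scattering correction
#'
#' Inverse-direction analogue of MSC: the reference is regressed on each
#' spectrum, `reference ~ a' + b' * x`, and the corrected spectrum is the
#' fitted value `a' + b' * x`.
#'
#' @inheritParams msc
#' @return Same type as `x`, corrected.
#' @export
isc <- function(x, reference = NULL) {
    M <- asSpectraMatrix(x)
    if (is.null(reference)) reference <- colMeans(M)
    mu_x <- rowMeans(M)
    var_x <- rowSums(sweep(M, 1, mu_x)^2)
    if (any(var_x <= 0)) stop("degenerate input: constant spectrum")
    cov_xr <- as.numeric(sweep(M, 1, mu_x) %*% (reference - mean(reference)))
    b <- cov_xr / var_x
    if (any(abs(b) < 1e-12)) stop("degenerate ISC fit: |b'| < 1e-12")
    a <- mean(reference) - b * mu_x
    out <- sweep(M * b, 1, a, "+")
    res <- replaceSpectra(x, out)
    if (is.numeric(x) && !is.matrix(x)) drop(res) else res
}

#' Extended inverse scattering correction
#'
#' Fits `reference ~ a' + b' * x + sum_k c'_k t^k` per spectrum and corrects
#' by the fitted value.
#'
#' @inheritParams emsc
#' @return Same type as `x`, corrected.
#' @export
eisc <- function(x, reference = NULL, wl = NULL, degree = 2) {
    M <- asSpectraMatrix(x)
    if (is.null(wl)) wl <- if (is(x, "SpectraSet")) wavelengths(x) else seq_len(ncol(M))
    if (is.null(reference)) reference <- colMeans(M)
    P <- polyBasis(wl, degree)
    out <- M
    for (i in seq_len(nrow(M))) {
        D <- cbind(P, M[i, ])
        qrD <- qr(D)
        if (qrD$rank < ncol(D)) stop("rank-deficient EISC design for row ", i)
        cf <- qr.coef(qrD, reference)
        if (abs(cf[length(cf)]) < 1e-12) stop("degenerate EISC fit: |b'| < 1e-12")
        out[i, ] <- D %*% cf
    }
    res <- replaceSpectra(x, out)
    if (is.numeric(x) && !is.matrix(x)) drop(res) else res
}

#' Polynomial detrending
#'
#' Removes the least-squares polynomial (in normalized wavelength) of the
#' given degree from each spectrum; the residual is orthogonal to the
#' polynomial basis and has zero mean for `degree >= 0`.
#'
#' @inheritParams emsc
#' @param degree polynomial degree (default 2).
#' @return Same type as `x`, detrended.
#' @export
detrendSpectra <- function(x, wl = NULL, degree = 2) {
    M <- asSpectraMatrix(x)
    if (degree >= ncol(M)) stop("degree must be smaller than spectrum length")
    if (is.null(wl)) wl <- if (is(x, "SpectraSet")) wavelengths(x) else seq_len(ncol(M))
    Q <- qr.Q(qr(polyBasis(wl, degree)))
    out <- M - (M %*% Q) %*% t(Q)
    res <- replaceSpectra(x, out)
    if (is.numeric(x) && !is.matrix(x)) drop(res) else res
}

#' Build a PreprocessScheme
#'
#' @param schemeId unique identifier.
#' @param steps list of steps, each `list(name = , params = list())`.
#' @return A [PreprocessScheme-class].
#' @export
preprocessScheme <- function(schemeId, steps = list()) {
    new("PreprocessScheme", schemeId = schemeId, steps = steps)
}

#' @describeIn preprocessScheme Scheme identifier.
#' @param object a `PreprocessScheme`.
#' @export
setMethod("schemeId", "PreprocessScheme", function(object) object@schemeId)

#' @describeIn preprocessScheme Ordered list of steps.
#' @export
setMethod("schemeSteps", "PreprocessScheme", function(object) object@steps)

#' @export
#' @noRd
setMethod("show", "PreprocessScheme", function(object) {
    nm <- vapply(object@steps, function(s) s$name, character(1))
    cat(sprintf("PreprocessScheme '%s': %s\n", object@schemeId,
                if (length(nm)) paste(nm, collapse = " -> ") else "(identity)"))
})

#' @export
#' @noRd
setMethod("show", "FittedScheme", function(object) {
    cat("FittedScheme of ")
    show(object@scheme)
})

#' Default preprocessing catalogue
#'
#' Crosses a Savitzky-Golay stage (none, smoothing, 1st derivative, 2nd
#' derivative; window 15, 2nd-degree polynomial), a scatter/baseline stage
#' (none, SNV, MSC, EMSC, ISC, EISC, detrending) and optional unit-variance
#' column scaling, applied in that order. The default configuration yields
#' exactly 7 x 4 x 2 = 56 distinct schemes; the raw-spectra scheme has id
#' `"none"`.
#'
#' @param scatter character vector of scatter-stage options (subset of
#'   `none`, `snv`, `msc`, `emsc`, `isc`, `eisc`, `detrend`).
#' @param sg character vector of SG-stage options (subset of `none`,
#'   `smooth`, `d1`, `d2`).
#' @param unitVariance logical vector of unit-variance options.
#' @param window,polyorder SG filter parameters.
#' @return List of [PreprocessScheme-class], deterministic order,
#'   duplicate-free.
#' @export
buildCatalogue <- function(scatter = c("none", "snv", "msc", "emsc", "isc",
                                       "eisc", "detrend"),
                           sg = c("none", "smooth", "d1", "d2"),
                           unitVariance = c(FALSE, TRUE),
                           window = 15, polyorder = 2) {
    schemes <- list()
    for (u in unitVariance) for (sc in scatter) for (g in sg) {
        steps <- list()
        id <- character()
        if (g == "smooth") {
            steps <- c(steps, list(list(name = "sg_smooth",
                params = list(window = window, polyorder = polyorder))))
            id <- c(id, "sg0")
        } else if (g %in% c("d1", "d2")) {
            steps <- c(steps, list(list(name = "sg_derivative",
                params = list(window = window, polyorder = polyorder,
                              derivOrder = if (g == "d1") 1 else 2))))
            id <- c(id, g)
        }
        if (sc != "none") {
            steps <- c(steps, list(list(name = if (sc == "detrend") "detrend" else sc,
                                        params = list())))
            id <- c(id, sc)
        }
        if (u) {
            steps <- c(steps, list(list(name = "unit_variance", params = list())))
            id <- c(id, "uv")
        }
        sid <- if (length(id)) paste(id, collapse = "+") else "none"
        schemes[[length(schemes) + 1L]] <- preprocessScheme(sid, steps)
    }
    ids <- vapply(schemes, schemeId, character(1))
    if (anyDuplicated(ids)) stop("duplicate scheme_id in catalogue")
    schemes
}

# Apply one step to a matrix; learn parameters if `learn` is TRUE, else use
# `learned`. Returns list(M, learned).
.applyStep <- function(step, M, wl, spacing, learn, learned = NULL) {
    nm <- step$name
    par <- step$params
    if (nm == "snv") {
        list(M = snv(M), learned = NULL)
    } else if (nm %in% c("sg_smooth", "sg_derivative")) {
        dv <- if (nm == "sg_smooth") 0 else par$derivOrder
        list(M = sgFilter(M, window = par$window %||% 15,
                          polyorder = par$polyorder %||% 2,
                          derivOrder = dv, spacing = spacing),
             learned = NULL)
    } else if (nm %in% c("msc", "emsc", "isc", "eisc")) {
        ref <- if (learn) colMeans(M) else learned$reference
        M2 <- switch(nm,
            msc = msc(M, reference = ref),
            emsc = emsc(M, reference = ref, wl = wl),
            isc = isc(M, reference = ref),
            eisc = eisc(M, reference = ref, wl = wl))
        list(M = M2, learned = list(reference = ref))
    } else if (nm == "detrend") {
        list(M = detrendSpectra(M, wl = wl, degree = par$degree %||% 2),
             learned = NULL)
    } else if (nm == "unit_variance") {
        sds <- if (learn) colSds(M) else learned$scales
        if (any(sds <= 0)) stop("zero-variance column in unit-variance scaling")
        list(M = sweep(M, 2, sds, "/"), learned = list(scales = sds))
    } else stop("unknown step: ", nm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a preprocessing scheme on training spectra
#'
#' Runs the scheme's steps in order on the training set, learning the
#' data-dependent parameters (MSC/EMSC/ISC/EISC reference = mean training
#' spectrum after the preceding steps; unit-variance scales = training
#' column SDs) from the training rows only.
#'
#' @param scheme a [PreprocessScheme-class].
#' @param train training spectra ([SpectraSet-class] or matrix).
#' @param wl wavelength grid (required for a matrix when the scheme uses
#'   wavelength-dependent steps).
#' @return List with elements `train` (transformed training set, same type
#'   as input) and `fitted` (a [FittedScheme-class]).
#' @export
fitScheme <- function(scheme, train, wl = NULL) {
    M <- asSpectraMatrix(train)
    if (nrow(M) == 0) stop("training set is empty")
    if (is.null(wl)) wl <- if (is(train, "SpectraSet")) wavelengths(train) else seq_len(ncol(M))
    spacing <- if (isUniform(wl)) diff(wl)[1] else NA_real_
    learned <- vector("list", length(scheme@steps))
    for (k in seq_along(scheme@steps)) {
        r <- .applyStep(scheme@steps[[k]], M, wl, spacing, learn = TRUE)
        M <- r$M
        learned[[k]] <- r$learned
    }
    list(train = replaceSpectra(train, M),
         fitted = new("FittedScheme", scheme = scheme, learned = learned,
                      wavelengths = as.numeric(wl)))
}

#' Apply a fitted preprocessing scheme to new spectra
#'
#' Replays the scheme with the training-learned parameters unchanged; no
#' parameter is re-estimated from `x`.
#'
#' @param fitted a [FittedScheme-class] from [fitScheme()].
#' @param x spectra to transform ([SpectraSet-class] or matrix).
#' @return Transformed spectra, same type as `x`.
#' @export
applyScheme <- function(fitted, x) {
    stopifnot(is(fitted, "FittedScheme"))
    M <- asSpectraMatrix(x)
    wl <- fitted@wavelengths
    if (ncol(M) != length(wl)) stop("wavelength count mismatch")
    spacing <- if (isUniform(wl)) diff(wl)[1] else NA_real_
    for (k in seq_along(fitted@scheme@steps)) {
        r <- .applyStep(fitted@scheme@steps[[k]], M, wl, spacing,
                        learn = FALSE, learned = fitted@learned[[k]])
        M <- r$M
    }
    replaceSpectra(x, M)
}

#' Fit a scheme on training spectra and apply it to other sets
#'
#' @inheritParams fitScheme
#' @param others list of spectra sets to transform with the
#'   training-learned parameters.
#' @return List with `train`, `others` (list of transformed sets) and
#'   `fitted`.
#' @export
fitApplyScheme <- function(scheme, train, others = list(), wl = NULL) {
    r <- fitScheme(scheme, train, wl = wl)
    out <- lapply(others, function(o) applyScheme(r$fitted, o))
    list(train = r$train, others = out, fitted = r$fitted)
}
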