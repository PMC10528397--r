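#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Principal component analysis of a spectra matrix
#'
#' Computed via singular value decomposition of the column-centered matrix.
#' The sign of each loading vector is fixed so that its largest-magnitude
#' element is positive, making score plots reproducible across platforms.
#'
#' @param x spectra ([SpectraSet-class] or samples-by-wavelengths matrix).
#' @param ncomp number of components (`<= min(n - 1, p)`).
#' @return A [PCAModel-class].
#' @export
fitPCA <- function(x, ncomp = 2) {
    X <- asSpectraMatrix(x)
    n <- nrow(X); p <- ncol(X)
    if (ncomp < 1 || ncomp > min(n - 1, p))
        stop("ncomp must lie in [1, min(n - 1, p)]")
    center <- colMeans(X)
    Xc <- sweep(X, 2, center)
    sv <- svd(Xc, nu = ncomp, nv = ncomp)
    V <- sv$v
    flip <- vapply(seq_len(ncomp), function(k) {
        j <- which.max(abs(V[, k]))
        if (V[j, k] < 0) -1 else 1
    }, numeric(1))
    V <- sweep(V, 2, flip, "*")
    scores <- Xc %*% V
    ev <- (sv$d[seq_len(ncomp)])^2 / (n - 1)
    total <- sum(sv$d^2) / (n - 1)
    new("PCAModel", center = center, loadings = V, scores = scores,
        explainedVariance = ev, varPercent = 100 * ev / total)
}

#' @describeIn fitPCA Loading matrix (wavelengths x components).
#' @param object a `PCAModel`.
#' @export
setMethod("loadings", "PCAModel", function(object, ...) object@loadings)

#' @describeIn fitPCA Score matrix (samples x components).
#' @export
setMethod("scores", "PCAModel", function(object, ...) object@scores)

#' @describeIn fitPCA Percentage of total variance per component.
#' @export
setMethod("explainedVariance", "PCAModel", function(object, ...) object@varPercent)

#' @export
#' @noRd
setMethod("show", "PCAModel", function(object) {
    cat(sprintf("PCAModel: %d components on %d wavelengths\n",
                ncol(object@loadings), length(object@center)))
    cat("variance explained (%):",
        paste(sprintf("%.2f", object@varPercent), collapse = ", "), "\n")
})

# Regression-vector paths ------------------------------------------------

# PCR coefficient path: beta for every f in 1..fMax at once (single SVD).
# Returns list(beta = p x fMax, intercept = fMax, centerX, centerY).
pcrPath <- function(X, y, fMax) {
    n <- nrow(X); p <- ncol(X)
    if (fMax < 1 || fMax > min(n - 1, p))
        stop("f out of range [1, min(n - 1, p)]")
    centerX <- colMeans(X); centerY <- mean(y)
    Xc <- sweep(X, 2, centerX); yc <- y - centerY
    sv <- svd(Xc, nu = fMax, nv = fMax)
    d <- sv$d[seq_len(fMax)]
    pos <- d > max(sv$d[1], 1e-300) * 1e-12
    # gamma_k = t_k'y / d_k^2 (scores are orthogonal with norms d_k)
    gamma <- ifelse(pos, as.numeric(crossprod(sv$u, yc)) * d / pmax(d^2, 1e-300), 0)
    beta <- apply_cumpath(sv$v, gamma)
    list(beta = beta, intercept = centerY - as.numeric(crossprod(beta, centerX)),
         centerX = centerX, centerY = centerY)
}

# Cumulative sum of rank-1 contributions V[,k] * gamma[k]: column f is the
# coefficient vector using the first f components.
apply_cumpath <- function(V, gamma) {
    B <- sweep(V, 2, gamma, "*")
    if (ncol(B) == 1L) return(B)
    t(apply(B, 1, cumsum))
}

# NIPALS PLS1 coefficient path with X-deflation. Returns beta path plus the
# W, P, q factors. `center` toggles column centering of X and y (disabled for
# the one-class decomposition). Stops early with a warning if the residual
# covariance X'y vanishes.
plsPath <- function(X, y, fMax, center = TRUE, tol = 1e-12, maxiter = 500) {
    n <- nrow(X); p <- ncol(X)
    if (fMax < 1 || fMax > min(n - if (center) 1 else 0, p))
        stop("f out of range")
    if (center) {
        centerX <- colMeans(X); centerY <- mean(y)
        Xk <- sweep(X, 2, centerX); yk <- y - centerY
    } else {
        centerX <- rep(0, p); centerY <- 0
        Xk <- X; yk <- y
    }
    W <- matrix(0, p, fMax); P <- matrix(0, p, fMax)
    Q <- numeric(fMax); Tm <- matrix(0, n, fMax)
    actual <- 0L
    for (k in seq_len(fMax)) {
        w <- as.numeric(crossprod(Xk, yk))
        nw <- sqrt(sum(w^2))
        if (nw < 1e-14) {
            warning("zero covariance after ", k - 1L,
                    " components; f reduced to ", k - 1L)
            break
        }
        w <- w / nw
        t <- as.numeric(Xk %*% w)
        tt <- sum(t^2)
        pk <- as.numeric(crossprod(Xk, t)) / tt
        qk <- sum(yk * t) / tt
        Xk <- Xk - tcrossprod(t, pk)
        W[, k] <- w; P[, k] <- pk; Q[k] <- qk; Tm[, k] <- t
        actual <- k
    }
    if (actual == 0L) stop("response has no covariance with the spectra")
    W <- W[, seq_len(actual), drop = FALSE]
    P <- P[, seq_len(actual), drop = FALSE]
    Q <- Q[seq_len(actual)]
    Tm <- Tm[, seq_len(actual), drop = FALSE]
    # beta_f = W_f (P_f' W_f)^-1 q_f for every f; build incrementally via
    # back-substitution on the (upper-triangular in NIPALS) P'W matrix.
    beta <- matrix(0, p, actual)
    PtW <- crossprod(P, W)
    for (f in seq_len(actual)) {
        bf <- solve(PtW[seq_len(f), seq_len(f), drop = FALSE], Q[seq_len(f)])
        beta[, f] <- W[, seq_len(f), drop = FALSE] %*% bf
    }
    list(beta = beta,
         intercept = centerY - as.numeric(crossprod(beta, centerX)),
         centerX = centerX, centerY = centerY,
         W = W, P = P, q = Q, scores = Tm, f = actual)
}

.newLatentModel <- function(kind, f, path, X, y) {
    f_use <- min(f, ncol(path$beta))
    beta <- path$beta[, f_use]
    intercept <- path$intercept[f_use]
    new("LatentRegressionModel", kind = kind, f = as.integer(f_use),
        centerX = path$centerX, centerY = path$centerY, beta = beta,
        intercept = intercept,
        fitted = as.numeric(X %*% beta + intercept))
}

#' Fit a principal component regression model
#'
#' Ordinary least squares of the (centered) response on the first `f`
#' principal component scores of the column-centered spectra; the coefficient
#' vector is folded back to wavelength space.
#'
#' @param x spectra ([SpectraSet-class] or matrix).
#' @param y response (adulterant fraction, % w/w); taken from the
#'   `SpectraSet` metadata when omitted.
#' @param f number of latent variables.
#' @return A [LatentRegressionModel-class].
#' @export
fitPCR <- function(x, y = NULL, f = 2) {
    X <- asSpectraMatrix(x); y <- responseOf(x, y)
    .newLatentModel("pcr", f, pcrPath(X, y, f), X, y)
}

#' Fit a partial least squares regression model (PLS1, NIPALS)
#'
#' Latent variables maximize the covariance between spectral scores and the
#' response: iteratively `w_k = X_k'y / ||X_k'y||`, `t_k = X_k w_k`, loadings
#' `p_k = X_k't_k / t_k't_k`, `q_k = y't_k / t_k't_k`, with X-deflation.
#' X and y are column mean-centered before decomposition.
#'
#' @inheritParams fitPCR
#' @return A [LatentRegressionModel-class].
#' @export
fitPLSR <- function(x, y = NULL, f = 2) {
    X <- asSpectraMatrix(x); y <- responseOf(x, y)
    .newLatentModel("plsr", f, plsPath(X, y, f), X, y)
}

#' @describeIn fitPCR Regression vector in wavelength space.
#' @param object a `LatentRegressionModel`.
#' @export
setMethod("coefVector", "LatentRegressionModel", function(object) object@beta)

#' @describeIn fitPCR Model intercept.
#' @export
setMethod("modelIntercept", "LatentRegressionModel", function(object) object@intercept)

#' @describeIn fitPCR Number of latent variables.
#' @export
setMethod("nComponents", "LatentRegressionModel", function(object) object@f)

#' @export
#' @noRd
setMethod("show", "LatentRegressionModel", function(object) {
    cat(sprintf("%s model, f = %d latent variable(s), %d wavelengths\n",
                toupper(object@kind), object@f, length(object@beta)))
})

#' Predict adulterant concentration from spectra
#'
#' Linear prediction `X %*% beta + intercept`. Predictions are not clipped
#' and may fall outside [0, 100].
#'
#' @param object a [LatentRegressionModel-class].
#' @param newdata spectra ([SpectraSet-class] or matrix) with the training
#'   wavelength count.
#' @return Numeric vector of predicted concentrations (% w/w).
#' @export
setMethod("predict", "LatentRegressionModel", function(object, newdata, ...) {
    X <- asSpectraMatrix(newdata)
    if (ncol(X) != length(object@beta))
        stop("wavelength count mismatch: model has ", length(object@beta))
    as.numeric(X %*% object@beta + object@intercept)
})
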