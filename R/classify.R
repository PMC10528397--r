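#' @include AllClasses.R latent.R utils.R
#' @importFrom stats qf qchisq
NULL

#' Fit a two-class PLS-DA model
#'
#' PLSR on a class code: the two labels (sorted alphabetically) are coded -1
#' and +1 and the coded response is modeled by NIPALS PLS1. The decision
#' rule is hard: continuous score `>= threshold` (default 0) is assigned to
#' the +1 class, ties included.
#'
#' @param x spectra ([SpectraSet-class] or matrix).
#' @param labels class label per sample (exactly two distinct values); for a
#'   `SpectraSet` the `adulterant` column is used when omitted.
#' @param f number of latent variables.
#' @param threshold decision threshold on the continuous score.
#' @return A [DiscriminantModel-class].
#' @export
fitPLSDA <- function(x, labels = NULL, f = 2, threshold = 0) {
    X <- asSpectraMatrix(x)
    if (is.null(labels)) {
        if (!is(x, "SpectraSet")) stop("labels must be supplied for a matrix")
        labels <- sampleMeta(x)$adulterant
    }
    labels <- as.character(labels)
    lv <- sort(unique(labels))
    if (length(lv) != 2)
        stop("exactly two classes are required, got ", length(lv))
    y <- ifelse(labels == lv[2], 1, -1)
    base <- .newLatentModel("plsr", f, plsPath(X, y, f), X, y)
    new("DiscriminantModel", base = base, threshold = threshold,
        classMap = stats::setNames(lv, c("-1", "+1")))
}

#' @export
#' @noRd
setMethod("show", "DiscriminantModel", function(object) {
    cat(sprintf("PLS-DA model, f = %d: '%s' (-1) vs '%s' (+1), threshold %g\n",
                object@base@f, object@classMap[["-1"]],
                object@classMap[["+1"]], object@threshold))
})

#' Predict classes with a PLS-DA model
#'
#' @param model a [DiscriminantModel-class].
#' @param x spectra to classify.
#' @return `data.frame` with columns `score` (continuous PLS prediction of
#'   the class code) and `label` (hard assignment; ties go to the +1
#'   class).
#' @export
predictPLSDA <- function(model, x) {
    stopifnot(is(model, "DiscriminantModel"))
    sc <- predict(model@base, x)
    lab <- ifelse(sc >= model@threshold, model@classMap[["+1"]],
                  model@classMap[["-1"]])
    data.frame(score = sc, label = lab, stringsAsFactors = FALSE)
}

#' Fit a one-class PLS model
#'
#' Latent decomposition of the target-class spectra by NIPALS PLS against a
#' constant unit response (X uncentered, so the first component absorbs the
#' class mean). Two soft acceptance rules are calibrated on the training
#' scores and residuals, each at level `alpha/2`:
#' \itemize{
#'   \item score distance `d_i^2 = sum_k (t_ik - tbar_k)^2 / s_k^2`
#'     (diagonal Mahalanobis; NIPALS scores are orthogonal) against the
#'     F-based Hotelling-type limit
#'     `f (n^2 - 1) / (n (n - f)) * F(1 - alpha/2; f, n - f)`;
#'   \item squared reconstruction residual `q_i = ||x_i - t_i P'||^2`
#'     against the Box scaled-chi-square limit `g * chi^2_h(1 - alpha/2)`
#'     with `g = v / (2 m)`, `h = 2 m^2 / v` (m, v = training mean and
#'     variance of q).
#' }
#' A sample is accepted only when both statistics fall below their limits.
#'
#' @param x target-class spectra ([SpectraSet-class] or matrix), `n > f + 1`.
#' @param f number of latent variables.
#' @param alpha nominal false-rejection rate (default 0.05).
#' @return A [OneClassModel-class].
#' @export
fitOCPLS <- function(x, f = 2, alpha = 0.05) {
    X <- asSpectraMatrix(x)
    n <- nrow(X)
    if (n <= f + 1) stop("need n > f + 1 target samples")
    path <- plsPath(X, rep(1, n), f, center = FALSE)
    f <- path$f
    W <- path$W; P <- path$P
    R <- W %*% solve(crossprod(P, W))
    Tm <- X %*% R
    mu <- colMeans(Tm)
    sds <- colSds(Tm)
    if (any(sds <= 0)) stop("degenerate score variance")
    d2 <- rowSums(sweep(sweep(Tm, 2, mu), 2, sds, "/")^2)
    dCrit <- f * (n^2 - 1) / (n * (n - f)) * stats::qf(1 - alpha / 2, f, n - f)
    q <- rowSums((X - Tm %*% t(P))^2)
    m <- mean(q); v <- stats::var(q)
    if (v <= 0) stop("degenerate residual distribution")
    g <- v / (2 * m); h <- 2 * m^2 / v
    qCrit <- g * stats::qchisq(1 - alpha / 2, h)
    new("OneClassModel", weights = W, projection = R, loadings = P,
        scoreMeans = mu, scoreSD = sds, dCrit = dCrit, qCrit = qCrit,
        alpha = alpha, f = as.integer(f))
}

#' @export
#' @noRd
setMethod("show", "OneClassModel", function(object) {
    cat(sprintf(
        "OC-PLS model, f = %d, alpha = %g: d2 <= %.4g AND q <= %.4g\n",
        object@f, object@alpha, object@dCrit, object@qCrit))
})

#' Evaluate spectra against a one-class PLS model
#'
#' Soft verdict per sample: with several `OneClassModel`s a sample may be
#' accepted by any number of them (including none).
#'
#' @param model a [OneClassModel-class].
#' @param x spectra to evaluate.
#' @param thresholdScale optional scalar (or length-2 vector for d2/q)
#'   multiplying the acceptance thresholds; used for diagnostic curves.
#' @return `data.frame` with columns `d2`, `q` and logical `accepted`.
#' @export
predictOCPLS <- function(model, x, thresholdScale = 1) {
    stopifnot(is(model, "OneClassModel"))
    X <- asSpectraMatrix(x)
    if (ncol(X) != nrow(model@weights)) stop("wavelength count mismatch")
    ts <- rep(thresholdScale, length.out = 2)
    Tm <- X %*% model@projection
    d2 <- rowSums(sweep(sweep(Tm, 2, model@scoreMeans), 2, model@scoreSD, "/")^2)
    q <- rowSums((X - Tm %*% t(model@loadings))^2)
    data.frame(d2 = d2, q = q,
               accepted = d2 <= ts[1] * model@dCrit & q <= ts[2] * model@qCrit)
}
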