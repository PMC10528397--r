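#' @include AllClasses.R latent.R classify.R preprocess.R utils.R
NULL

#' Root mean squared error
#'
#' @param yObs,yPred observed and predicted responses (equal, nonzero
#'   length).
#' @return `sqrt(mean((yObs - yPred)^2))`, in response units.
#' @export
rmse <- function(yObs, yPred) {
    if (length(yObs) == 0 || length(yObs) != length(yPred))
        stop("yObs and yPred must have equal nonzero length")
    sqrt(mean((yObs - yPred)^2))
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot` with the total sum of squares about the mean of
#' `yObs` in the same set (not a squared correlation, so bias is penalized
#' and worse-than-mean predictions give negative values).
#'
#' @inheritParams rmse
#' @return Numeric scalar `<= 1`.
#' @export
rSquared <- function(yObs, yPred) {
    if (length(yObs) == 0 || length(yObs) != length(yPred))
        stop("yObs and yPred must have equal nonzero length")
    sst <- sum((yObs - mean(yObs))^2)
    if (sst <= 0) stop("constant yObs: R^2 undefined")
    1 - sum((yObs - yPred)^2) / sst
}

#' RMSEP relative to the calibration range
#'
#' @param rmsep root mean squared error of prediction (response units).
#' @param calibrationRange width of the calibration design,
#'   `max(y) - min(y)`.
#' @return `100 * rmsep / calibrationRange`, in percent.
#' @export
relativeRMSEP <- function(rmsep, calibrationRange) {
    if (calibrationRange <= 0) stop("calibration range must be > 0")
    100 * rmsep / calibrationRange
}

#' Classification figures of merit from confusion counts
#'
#' CCR = 100 (TP + TN) / total, sensitivity = 100 TP / (TP + FN),
#' specificity = 100 TN / (TN + FP). A metric whose denominator is zero is
#' returned as `NA` with a warning rather than silently as 0.
#'
#' @param TP,TN,FP,FN non-negative confusion counts.
#' @return Named numeric vector `c(CCR, sensitivity, specificity)` in
#'   percent.
#' @export
classificationMetrics <- function(TP, TN, FP, FN) {
    counts <- c(TP = TP, TN = TN, FP = FP, FN = FN)
    if (any(counts < 0)) stop("confusion counts must be non-negative")
    total <- sum(counts)
    if (total == 0) stop("no samples: metrics undefined")
    ccr <- 100 * (TP + TN) / total
    sens <- if (TP + FN > 0) 100 * TP / (TP + FN) else {
        warning("sensitivity undefined: TP + FN = 0"); NA_real_
    }
    spec <- if (TN + FP > 0) 100 * TN / (TN + FP) else {
        warning("specificity undefined: TN + FP = 0"); NA_real_
    }
    c(CCR = ccr, sensitivity = sens, specificity = spec)
}

# Confusion counts from labels, `positive` being the +1 class.
.confusion <- function(truth, predicted, positive) {
    TP <- sum(truth == positive & predicted == positive)
    TN <- sum(truth != positive & predicted != positive)
    FP <- sum(truth != positive & predicted == positive)
    FN <- sum(truth == positive & predicted != positive)
    c(TP = TP, TN = TN, FP = FP, FN = FN)
}

#' Leave-one-out cross-validation of a calibration model
#'
#' For each left-out sample the model — and, when a preprocessing scheme is
#' given, the scheme's training-learned parameters — is refitted on the
#' remaining samples and the left-out response predicted, for every
#' complexity `f = 1..fMax` in one pass.
#'
#' @param x spectra ([SpectraSet-class] or matrix); raw (un-preprocessed)
#'   when `scheme` is given.
#' @param y response; from metadata when omitted.
#' @param kind `"plsr"` or `"pcr"`.
#' @param fMax largest complexity examined (`<= min(n - 2, p)`).
#' @param scheme optional [PreprocessScheme-class], refitted inside every
#'   fold.
#' @param wl wavelength grid for a plain matrix with a wavelength-dependent
#'   scheme.
#' @return Numeric vector `RMSECV[f]`, `f = 1..fMax`.
#' @export
looCV <- function(x, y = NULL, kind = c("plsr", "pcr"), fMax = 10,
                  scheme = NULL, wl = NULL) {
    kind <- match.arg(kind)
    X <- asSpectraMatrix(x); y <- responseOf(x, y)
    n <- nrow(X)
    if (n < 3) stop("need at least 3 samples")
    if (fMax > min(n - 2, ncol(X))) stop("fMax out of range")
    if (is.null(wl)) wl <- if (is(x, "SpectraSet")) wavelengths(x) else seq_len(ncol(X))
    pred <- matrix(NA_real_, n, fMax)
    for (i in seq_len(n)) {
        Xtr <- X[-i, , drop = FALSE]; ytr <- y[-i]
        Xte <- X[i, , drop = FALSE]
        if (!is.null(scheme)) {
            fs <- fitScheme(scheme, Xtr, wl = wl)
            Xtr <- fs$train
            Xte <- applyScheme(fs$fitted, Xte)
        }
        path <- if (kind == "plsr") plsPath(Xtr, ytr, fMax) else pcrPath(Xtr, ytr, fMax)
        fa <- ncol(path$beta)
        pr <- as.numeric(Xte %*% path$beta) + path$intercept
        pred[i, seq_len(fa)] <- pr
        if (fa < fMax) pred[i, (fa + 1):fMax] <- pr[fa]
    }
    vapply(seq_len(fMax), function(f) rmse(y, pred[, f]), numeric(1))
}

#' Parsimonious complexity selection from an RMSECV curve
#'
#' Returns the smallest `f` whose RMSECV is within `tolerance` (relative) of
#' the curve minimum, guarding against over-optimistic large-f models.
#'
#' @param rmsecv numeric vector, RMSECV per `f = 1..length(rmsecv)`.
#' @param tolerance relative tolerance above the minimum (default 0.02).
#' @return Selected complexity `f`.
#' @export
selectComplexity <- function(rmsecv, tolerance = 0.02) {
    if (!length(rmsecv)) stop("empty RMSECV curve")
    which(rmsecv <= (1 + tolerance) * min(rmsecv))[1]
}

#' Monte Carlo validation of a PLS-DA model
#'
#' Implements the resampling protocol of the discrimination study: at each
#' iteration `trainPerGroup` samples per group are drawn without replacement
#' from the model set (stratified), the preprocessing scheme (if any) and the
#' PLS-DA model are refitted on that draw, and CCR, sensitivity and
#' specificity are evaluated on the training draw, the remaining internal
#' test samples, and the fixed external validation set. Means and SDs (n-1)
#' across iterations are reported in percent. The +1 (positive) class is the
#' alphabetically larger label.
#'
#' @param modelSet [SpectraSet-class] with both groups (model samples).
#' @param validationSet [SpectraSet-class] with both groups (external
#'   validation samples).
#' @param f PLS-DA complexity.
#' @param iterations number of Monte Carlo iterations (default 500).
#' @param trainPerGroup training draw size per group (default 35).
#' @param seed integer seed; the report is a pure function of it.
#' @param scheme optional [PreprocessScheme-class] refitted on every
#'   training draw.
#' @param groups name of the metadata column holding the group label.
#' @return An [MCReport-class].
#' @export
monteCarloValidate <- function(modelSet, validationSet, f = 7,
                               iterations = 500, trainPerGroup = 35,
                               seed = 1, scheme = NULL,
                               groups = "adulterant") {
    gM <- sampleMeta(modelSet)[[groups]]
    gV <- sampleMeta(validationSet)[[groups]]
    lv <- sort(unique(gM))
    if (length(lv) != 2) stop("model set must contain exactly two groups")
    if (!setequal(unique(gV), lv)) stop("validation set groups differ from model set")
    idx_by_group <- lapply(lv, function(g) which(gM == g))
    if (any(vapply(idx_by_group, length, integer(1)) <= trainPerGroup))
        stop("each group needs more than trainPerGroup model samples")
    X <- spectra(modelSet); XV <- spectra(validationSet)
    wl <- wavelengths(modelSet)
    positive <- lv[2]
    metrics <- c("CCR", "sensitivity", "specificity")
    sets <- c("training", "test", "validation")
    acc <- array(NA_real_, c(iterations, 3, 3), dimnames = list(NULL, metrics, sets))
    withSeed(seed, {
        for (it in seq_len(iterations)) {
            tr <- unlist(lapply(idx_by_group, function(ix) sample(ix, trainPerGroup)))
            te <- setdiff(seq_len(nrow(X)), tr)
            Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]; Xv <- XV
            if (!is.null(scheme)) {
                fs <- fitScheme(scheme, Xtr, wl = wl)
                Xtr <- fs$train
                Xte <- applyScheme(fs$fitted, Xte)
                Xv <- applyScheme(fs$fitted, XV)
            }
            mod <- fitPLSDA(Xtr, gM[tr], f = f)
            evalset <- list(training = list(Xtr, gM[tr]),
                            test = list(Xte, gM[te]),
                            validation = list(Xv, gV))
            for (s in seq_along(evalset)) {
                pr <- predictPLSDA(mod, evalset[[s]][[1]])$label
                cc <- .confusion(evalset[[s]][[2]], pr, positive)
                acc[it, , s] <- suppressWarnings(
                    classificationMetrics(cc["TP"], cc["TN"], cc["FP"], cc["FN"]))
            }
        }
    })
    mean_m <- apply(acc, c(2, 3), mean)
    sd_m <- if (iterations > 1) apply(acc, c(2, 3), stats::sd) else mean_m * 0
    new("MCReport", mean = mean_m, sd = sd_m,
        iterations = as.integer(iterations), f = as.integer(f),
        positiveClass = positive, degenerate = iterations == 1L)
}

#' @export
#' @noRd
setMethod("show", "MCReport", function(object) {
    cat(sprintf("Monte Carlo PLS-DA report: %d iteration(s), f = %d, positive class '%s'%s\n",
                object@iterations, object@f, object@positiveClass,
                if (object@degenerate) " [single iteration: SDs are 0]" else ""))
    tab <- matrix(sprintf("%.2f ± %.2f", object@mean, object@sd),
                  nrow(object@mean), dimnames = dimnames(object@mean))
    print(as.data.frame(tab))
})

#' Tabulate an MCReport
#'
#' @param x an [MCReport-class].
#' @param ... unused.
#' @return `data.frame` with one row per metric and mean/SD columns per set
#'   (training, internal test, external validation), in percent.
#' @export
mcReportTable <- function(x, ...) {
    stopifnot(is(x, "MCReport"))
    out <- data.frame(metric = rownames(x@mean))
    for (s in colnames(x@mean)) {
        out[[paste0(s, "_mean")]] <- x@mean[, s]
        out[[paste0(s, "_sd")]] <- x@sd[, s]
    }
    out
}

#' Write an MCReport as CSV
#'
#' @param x an [MCReport-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeMCReport <- function(x, path) {
    utils::write.csv(mcReportTable(x), path, row.names = FALSE)
    invisible(path)
}

#' Discrimination-rate curve over model complexity
#'
#' Runs [monteCarloValidate()] for every complexity in `fRange` and selects
#' the optimum as the `f` maximizing the mean internal-test CCR (ties go to
#' the smallest `f`; the internal test set is used so the external
#' validation set plays no part in selection).
#'
#' @inheritParams monteCarloValidate
#' @param fRange complexities to examine.
#' @return List with `curve` (`data.frame`: `f`, mean and SD of CCR per
#'   set) and `optimal` (selected `f`).
#' @export
complexityCurve <- function(modelSet, validationSet, fRange = 1:10,
                            iterations = 100, trainPerGroup = 35, seed = 1,
                            scheme = NULL) {
    rows <- lapply(fRange, function(f) {
        rep <- monteCarloValidate(modelSet, validationSet, f = f,
                                  iterations = iterations,
                                  trainPerGroup = trainPerGroup,
                                  seed = substreamSeed(seed, f),
                                  scheme = scheme)
        data.frame(f = f,
                   training_ccr = rep@mean["CCR", "training"],
                   training_sd = rep@sd["CCR", "training"],
                   test_ccr = rep@mean["CCR", "test"],
                   test_sd = rep@sd["CCR", "test"],
                   validation_ccr = rep@mean["CCR", "validation"],
                   validation_sd = rep@sd["CCR", "validation"])
    })
    curve <- do.call(rbind, rows)
    list(curve = curve, optimal = curve$f[which.max(curve$test_ccr)])
}
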