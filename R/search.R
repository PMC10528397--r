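#' @include AllClasses.R preprocess.R latent.R validation.R
NULL

#' Exhaustive preprocessing x model x complexity search
#'
#' For every scheme in the catalogue and each model kind, the scheme is
#' fitted on the calibration set only and applied to the validation set,
#' then one latent decomposition gives RMSEC/RMSEP/R2c/R2v for every
#' complexity `f = 1..fMax`. With the default 56-scheme catalogue and
#' `fMax = 15` this evaluates 840 candidate models per kind (1680 for both).
#' A failing scheme/complexity combination is recorded (`status = "failed"`,
#' NA figures) rather than aborting the grid.
#'
#' @param calibration,validation disjoint [SpectraSet-class]s (or matrices
#'   with `y` vectors via `yCal`/`yVal`).
#' @param catalogue list of [PreprocessScheme-class] (default
#'   [buildCatalogue()]).
#' @param modelKinds subset of `c("pcr", "plsr")`.
#' @param fMax largest complexity examined (default 15).
#' @param yCal,yVal responses when matrices are supplied.
#' @return `data.frame` with one row per (scheme, kind, f): columns
#'   `adulterant`, `scheme_id`, `model`, `f`, `rmsec`, `rmsep`, `r2c`,
#'   `r2v`, `status`; deterministic order.
#' @export
gridSearch <- function(calibration, validation,
                       catalogue = buildCatalogue(),
                       modelKinds = c("pcr", "plsr"), fMax = 15,
                       yCal = NULL, yVal = NULL) {
    modelKinds <- match.arg(modelKinds, several.ok = TRUE)
    Xc <- asSpectraMatrix(calibration); Xv <- asSpectraMatrix(validation)
    yc <- responseOf(calibration, yCal); yv <- responseOf(validation, yVal)
    wl <- if (is(calibration, "SpectraSet")) wavelengths(calibration)
          else seq_len(ncol(Xc))
    adult <- if (is(calibration, "SpectraSet")) {
        a <- setdiff(unique(sampleMeta(calibration)$adulterant), "none")
        if (length(a)) paste(a, collapse = "+") else "none"
    } else NA_character_
    rows <- list()
    for (scheme in catalogue) {
        sid <- schemeId(scheme)
        prep <- tryCatch(
            fitApplyScheme(scheme, Xc, others = list(Xv), wl = wl),
            error = function(e) e)
        for (kind in modelKinds) {
            fs <- seq_len(fMax)
            if (inherits(prep, "error")) {
                rows[[length(rows) + 1L]] <- data.frame(
                    adulterant = adult, scheme_id = sid, model = kind, f = fs,
                    rmsec = NA_real_, rmsep = NA_real_, r2c = NA_real_,
                    r2v = NA_real_, status = "failed",
                    stringsAsFactors = FALSE)
                next
            }
            res <- tryCatch({
                path <- if (kind == "plsr")
                    suppressWarnings(plsPath(prep$train, yc, fMax))
                else pcrPath(prep$train, yc, fMax)
                fa <- ncol(path$beta)
                predC <- sweep(prep$train %*% path$beta, 2, path$intercept, "+")
                predV <- sweep(prep$others[[1]] %*% path$beta, 2, path$intercept, "+")
                data.frame(
                    adulterant = adult, scheme_id = sid, model = kind,
                    f = seq_len(fa),
                    rmsec = vapply(seq_len(fa), function(f) rmse(yc, predC[, f]), 0),
                    rmsep = vapply(seq_len(fa), function(f) rmse(yv, predV[, f]), 0),
                    r2c = vapply(seq_len(fa), function(f) rSquared(yc, predC[, f]), 0),
                    r2v = vapply(seq_len(fa), function(f) rSquared(yv, predV[, f]), 0),
                    status = "ok", stringsAsFactors = FALSE)
            }, error = function(e) data.frame(
                adulterant = adult, scheme_id = sid, model = kind, f = fs,
                rmsec = NA_real_, rmsep = NA_real_, r2c = NA_real_,
                r2v = NA_real_, status = "failed", stringsAsFactors = FALSE))
            if (nrow(res) < fMax && all(res$status == "ok")) {
                extra <- res[rep(nrow(res), fMax - nrow(res)), ]
                extra$f <- (nrow(res) + 1L):fMax
                extra$status <- "reduced"
                res <- rbind(res, extra)
            }
            rows[[length(rows) + 1L]] <- res
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Select the optimal row of a search grid
#'
#' Formalizes "smallest errors, most comparable between calibration and
#' validation, fewest latent variables": rows whose calibration/validation
#' error gap satisfies `|rmsep - rmsec| <= comparabilityTol *
#' min(rmsec, rmsep)` are feasible (with a warning and fallback to all rows
#' if none are), then rows are ranked lexicographically by `(rmsep, f,
#' rmsec, scheme_id, model)` and the first is returned. The result is
#' invariant to the input row order.
#'
#' @param rows `data.frame` from [gridSearch()].
#' @param comparabilityTol maximum relative RMSEC/RMSEP gap (default 0.25).
#' @return The selected row (single-row `data.frame`).
#' @export
selectOptimal <- function(rows, comparabilityTol = 0.25) {
    ok <- rows[!is.na(rows$rmsec) & !is.na(rows$rmsep), , drop = FALSE]
    if (!nrow(ok)) stop("no successful rows")
    feas <- abs(ok$rmsep - ok$rmsec) <= comparabilityTol * pmin(ok$rmsec, ok$rmsep)
    if (!any(feas)) {
        warning("no row satisfies the comparability criterion; using all rows")
        feas <- rep(TRUE, nrow(ok))
    }
    ok <- ok[feas, , drop = FALSE]
    ok[order(ok$rmsep, ok$f, ok$rmsec, ok$scheme_id, ok$model), , drop = FALSE][1, ]
}

#' Write a search report as CSV
#'
#' Mirrors the result-table layout (adulterant, preprocessing, model, f,
#' RMSEC, RMSEP, R2c, R2v) with the selected row(s) flagged `optimal = "*"`.
#'
#' @param rows `data.frame` from [gridSearch()].
#' @param selected row(s) chosen by [selectOptimal()] (may be `NULL`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSearchReport <- function(rows, selected = NULL, path) {
    rows$optimal <- ""
    if (!is.null(selected) && nrow(selected)) {
        key <- function(d) paste(d$scheme_id, d$model, d$f)
        rows$optimal[key(rows) %in% key(selected)] <- "*"
    }
    utils::write.csv(rows, path, row.names = FALSE)
    invisible(path)
}

#' Predicted-versus-observed table for a calibration model
#'
#' One row per calibration and validation sample, ready for plotting a
#' predicted-vs-observed diagram.
#'
#' @param model a [LatentRegressionModel-class] fitted on the (preprocessed)
#'   calibration spectra.
#' @param calibration,validation (preprocessed) [SpectraSet-class]s.
#' @return `data.frame` with `sample_id`, `observed`, `predicted`, `set`.
#' @export
predictedVsObserved <- function(model, calibration, validation) {
    mk <- function(s, set) data.frame(
        sample_id = sampleMeta(s)$sample_id,
        observed = sampleMeta(s)$fraction,
        predicted = predict(model, s),
        set = set, stringsAsFactors = FALSE)
    rbind(mk(calibration, "calibration"), mk(validation, "validation"))
}
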