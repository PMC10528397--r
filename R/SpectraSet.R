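#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a SpectraSet
#'
#' @param X numeric matrix of absorbance values, samples in rows and
#'   wavelengths in columns.
#' @param wavelengths strictly increasing numeric vector of wavelengths (nm),
#'   one per column of `X`.
#' @param meta `data.frame` of per-sample metadata aligned to the rows of `X`.
#'   Missing standard columns are filled with defaults (`sample_id` =
#'   `S1, S2, ...`, `adulterant` = `"none"`, `fraction` = 0, `replicate` = 1,
#'   `set_label` = `"calibration"`).
#' @return A validated [SpectraSet-class].
#' @examples
#' s <- SpectraSet(matrix(rnorm(15), 3, 5), wavelengths = seq(1000, 1008, 2))
#' s
#' @export
SpectraSet <- function(X, wavelengths, meta = NULL) {
    X <- as.matrix(X)
    n <- nrow(X)
    if (length(wavelengths) != ncol(X))
        stop("length(wavelengths) must equal ncol(X)")
    if (is.null(meta)) meta <- data.frame(row.names = seq_len(max(n, 0)))[seq_len(n), , drop = FALSE]
    meta <- as.data.frame(meta, stringsAsFactors = FALSE)
    if (nrow(meta) != n) stop("meta must have one row per sample")
    if (is.null(meta$sample_id)) meta$sample_id <- sprintf("S%d", seq_len(n))
    if (is.null(meta$adulterant)) meta$adulterant <- rep("none", n)
    if (is.null(meta$fraction)) meta$fraction <- rep(0, n)
    if (is.null(meta$replicate)) meta$replicate <- rep(1L, n)
    if (is.null(meta$set_label)) meta$set_label <- rep("calibration", n)
    meta <- meta[, union(.META_COLS, colnames(meta)), drop = FALSE]
    rownames(X) <- meta$sample_id
    colnames(X) <- format(wavelengths, trim = TRUE)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(absorbance = t(X)),
        rowData = S4Vectors::DataFrame(wavelength = as.numeric(wavelengths)),
        colData = S4Vectors::DataFrame(meta, row.names = meta$sample_id))
    new("SpectraSet", se)
}

#' @describeIn SpectraSet Absorbance matrix, samples x wavelengths.
#' @param object a `SpectraSet`.
#' @export
setMethod("spectra", "SpectraSet", function(object, ...) {
    t(SummarizedExperiment::assay(object, "absorbance"))
})

#' @describeIn SpectraSet Wavelength grid in nm.
#' @export
setMethod("wavelengths", "SpectraSet", function(object, ...) {
    SummarizedExperiment::rowData(object)$wavelength
})

#' @describeIn SpectraSet Sample metadata as a `data.frame`.
#' @export
setMethod("sampleMeta", "SpectraSet", function(object, ...) {
    as.data.frame(SummarizedExperiment::colData(object))
})

#' @describeIn SpectraSet Number of samples.
#' @export
setMethod("nSamples", "SpectraSet", function(object) ncol(object))

#' @describeIn SpectraSet Number of wavelengths.
#' @export
setMethod("nWavelengths", "SpectraSet", function(object) nrow(object))

#' @describeIn SpectraSet `TRUE` when the wavelength grid is uniformly
#'   spaced (required by Savitzky-Golay filtering).
#' @export
setMethod("uniformSpacing", "SpectraSet", function(object) {
    isUniform(wavelengths(object))
})

isUniform <- function(wl, tol = 1e-8) {
    if (length(wl) < 2) return(TRUE)
    d <- diff(wl)
    max(abs(d - d[1])) <= tol * max(abs(d))
}

#' @export
#' @noRd
setMethod("show", "SpectraSet", function(object) {
    wl <- wavelengths(object)
    cat(sprintf("SpectraSet: %d samples x %d wavelengths (%g-%g nm%s)\n",
                nSamples(object), nWavelengths(object),
                if (length(wl)) min(wl) else NA, if (length(wl)) max(wl) else NA,
                if (uniformSpacing(object)) ", uniform grid" else ""))
    m <- sampleMeta(object)
    if (nrow(m)) {
        tab <- table(m$adulterant, m$set_label)
        cat("samples per adulterant x set:\n")
        print(tab)
    }
})

#' Subset a SpectraSet by set membership
#'
#' Returns the samples whose `set_label` equals `label`, preserving order.
#' The subsets over all labels present partition the original samples.
#'
#' @param object a [SpectraSet-class].
#' @param label one of `"calibration"`, `"validation"`, `"model"`,
#'   `"external"`.
#' @return A `SpectraSet` with the matching samples.
#' @export
setMethod("splitByLabel", "SpectraSet", function(object, label) {
    if (!label %in% .SET_LABELS)
        stop("unknown set label: ", label)
    keep <- sampleMeta(object)$set_label == label
    if (!any(keep))
        stop("no samples carry set label '", label, "'")
    object[, keep]
})

#' Concatenate SpectraSets sample-wise
#'
#' All sets must share the same wavelength grid; sample metadata rows are
#' stacked in order.
#'
#' @param ... [SpectraSet-class] objects.
#' @return A single [SpectraSet-class].
#' @export
bindSamples <- function(...) {
    sets <- list(...)
    stopifnot(length(sets) >= 1, all(vapply(sets, is, TRUE, "SpectraSet")))
    wl <- wavelengths(sets[[1]])
    for (s in sets[-1])
        if (!isTRUE(all.equal(wavelengths(s), wl)))
            stop("wavelength grids differ")
    X <- do.call(rbind, lapply(sets, spectra))
    meta <- do.call(rbind, lapply(sets, function(s)
        sampleMeta(s)[, .META_COLS, drop = FALSE]))
    SpectraSet(X, wl, meta)
}

#' Read spectra from a wide CSV file
#'
#' The interchange format is a wide CSV: the metadata columns `sample_id`,
#' `adulterant`, `fraction`, `replicate`, `set_label`, followed by one numeric
#' column per wavelength (header = wavelength in nm, ascending). UTF-8,
#' `.` decimal separator.
#'
#' @param path path to the CSV file.
#' @return A validated [SpectraSet-class]; wavelength order is preserved.
#' @export
readSpectra <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    meta_cols <- intersect(.META_COLS, colnames(df))
    if (!setequal(meta_cols, .META_COLS))
        stop("format error: missing metadata columns: ",
             paste(setdiff(.META_COLS, meta_cols), collapse = ", "))
    wl_cols <- setdiff(colnames(df), .META_COLS)
    wl <- suppressWarnings(as.numeric(wl_cols))
    if (anyNA(wl))
        stop("format error: non-numeric wavelength column header(s)")
    if (length(wl) >= 2 && any(diff(wl) <= 0))
        stop("format error: wavelengths must be strictly increasing")
    X <- as.matrix(df[, wl_cols, drop = FALSE])
    storage.mode(X) <- "double"
    if (nrow(X) > 0 && anyNA(X))
        stop("data error: missing absorbance values")
    if (anyDuplicated(df$sample_id))
        stop("data error: duplicate sample_id")
    meta <- df[, .META_COLS, drop = FALSE]
    meta$replicate <- as.integer(meta$replicate)
    SpectraSet(X, wl, meta)
}

#' Write spectra to a wide CSV file
#'
#' Numeric values are written with 15 significant digits so that a
#' read-write-read cycle is lossless at working precision and byte-stable on
#' the second cycle.
#'
#' @param s a [SpectraSet-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSpectra <- function(s, path) {
    stopifnot(is(s, "SpectraSet"))
    wl <- wavelengths(s)
    X <- spectra(s)
    meta <- sampleMeta(s)[, .META_COLS, drop = FALSE]
    header <- c(.META_COLS, sprintf("%.15g", wl))
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(paste(header, collapse = ","), con)
    if (nrow(X) > 0) {
        num <- matrix(sprintf("%.15g", X), nrow = nrow(X))
        lines <- vapply(seq_len(nrow(X)), function(i) {
            paste(c(meta$sample_id[i], meta$adulterant[i],
                    sprintf("%.15g", meta$fraction[i]),
                    as.character(meta$replicate[i]), meta$set_label[i],
                    num[i, ]), collapse = ",")
        }, character(1))
        writeLines(lines, con)
    }
    invisible(path)
}
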