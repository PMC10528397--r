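#' @import methods
#' @importFrom stats predict setNames var sd rnorm
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- assayNames rowData colData colData<-
#' @importFrom S4Vectors DataFrame
NULL

.ADULTERANTS <- c("none", "corn_flour", "corn_starch")
.SET_LABELS <- c("calibration", "validation", "model", "external")
.META_COLS <- c("sample_id", "adulterant", "fraction", "replicate", "set_label")

#' SpectraSet: absorbance spectra with sample metadata
#'
#' An S4 container for a set of near-infrared absorbance spectra, built on
#' [SummarizedExperiment::SummarizedExperiment]. The assay `"absorbance"`
#' holds the spectra as a wavelengths-by-samples matrix; `rowData` carries the
#' wavelength grid (nm); `colData` carries per-sample metadata with the fixed
#' columns `sample_id`, `adulterant` (`none`, `corn_flour` or `corn_starch`),
#' `fraction` (adulterant mass fraction, % w/w in `[0, 100]`), `replicate`
#' (positive integer) and `set_label` (`calibration`, `validation`, `model` or
#' `external`).
#'
#' The user-facing orientation is samples-by-wavelengths throughout:
#' [spectra()] returns the transposed assay.
#'
#' @slot .. inherits all slots from `SummarizedExperiment`.
#' @seealso [SpectraSet()], [readSpectra()], [writeSpectra()], [splitByLabel()]
#' @export
setClass("SpectraSet", contains = "SummarizedExperiment")

.validSpectraSet <- function(object) {
    msg <- character()
    if (!"absorbance" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'absorbance' is missing")
    rd <- SummarizedExperiment::rowData(object)
    if (!"wavelength" %in% colnames(rd)) {
        msg <- c(msg, "rowData column 'wavelength' is missing")
    } else {
        wl <- rd$wavelength
        if (length(wl) >= 2 && any(diff(wl) <= 0))
            msg <- c(msg, "wavelengths must be strictly increasing")
        if (length(wl) < 3)
            msg <- c(msg, "at least 3 wavelengths are required")
    }
    cd <- SummarizedExperiment::colData(object)
    missing_cols <- setdiff(.META_COLS, colnames(cd))
    if (length(missing_cols))
        msg <- c(msg, paste("missing metadata columns:",
                            paste(missing_cols, collapse = ", ")))
    if (nrow(cd) > 0 && "sample_id" %in% colnames(cd)) {
        if (anyDuplicated(cd$sample_id))
            msg <- c(msg, "duplicate sample_id")
    }
    if (nrow(cd) > 0 && "adulterant" %in% colnames(cd) &&
        !all(cd$adulterant %in% .ADULTERANTS))
        msg <- c(msg, paste("adulterant must be one of:",
                            paste(.ADULTERANTS, collapse = ", ")))
    if (nrow(cd) > 0 && "set_label" %in% colnames(cd) &&
        !all(cd$set_label %in% .SET_LABELS))
        msg <- c(msg, paste("set_label must be one of:",
                            paste(.SET_LABELS, collapse = ", ")))
    if (nrow(cd) > 0 && "fraction" %in% colnames(cd) &&
        (any(is.na(cd$fraction)) || any(cd$fraction < 0) || any(cd$fraction > 100)))
        msg <- c(msg, "fraction must lie in [0, 100]")
    if ("absorbance" %in% SummarizedExperiment::assayNames(object) &&
        anyNA(SummarizedExperiment::assay(object, "absorbance")))
        msg <- c(msg, "absorbance matrix contains missing values")
    if (length(msg)) msg else TRUE
}

setValidity("SpectraSet", .validSpectraSet)

#' EndmemberSpec: parametric pure-component spectrum
#'
#' Describes the absorbance spectrum of a pure powder (garlic or an
#' adulterant) as a sum of Gaussian absorption bands on a linear baseline.
#'
#' @slot name character, component name.
#' @slot bands numeric matrix with columns `center` (nm), `width` (nm, Gaussian
#'   sigma) and `amplitude` (AU); one row per absorption band.
#' @slot baselineOffset numeric, constant baseline (AU).
#' @slot baselineSlope numeric, linear baseline slope in AU per unit of
#'   normalized wavelength.
#' @export
setClass("EndmemberSpec",
    representation(name = "character", bands = "matrix",
                   baselineOffset = "numeric", baselineSlope = "numeric"))

setValidity("EndmemberSpec", function(object) {
    msg <- character()
    b <- object@bands
    if (nrow(b) > 0) {
        if (!all(c("center", "width", "amplitude") %in% colnames(b)))
            msg <- c(msg, "bands must have columns center, width, amplitude")
        else {
            if (any(b[, "amplitude"] < 0)) msg <- c(msg, "amplitudes must be >= 0")
            if (any(b[, "width"] <= 0)) msg <- c(msg, "widths must be > 0")
        }
    }
    if (length(msg)) msg else TRUE
})

#' NoiseModel: measurement and sample-preparation variability
#'
#' Parameters of the simulated distortions applied to clean mixture spectra:
#' multiplicative scatter gain (log-normal), additive offset, a linear
#' wavelength drift, i.i.d. per-channel noise, and replicate-level relative
#' perturbation of endmember band amplitudes.
#'
#' @slot scatterGainSD SD of the log multiplicative gain (dimensionless).
#' @slot scatterOffsetSD SD of the additive offset (AU).
#' @slot driftSD SD of the linear drift coefficient (AU per normalized nm).
#' @slot noiseSD SD of i.i.d. additive channel noise (AU).
#' @slot replicateSD relative SD of per-replicate band-amplitude perturbation.
#' @export
setClass("NoiseModel",
    representation(scatterGainSD = "numeric", scatterOffsetSD = "numeric",
                   driftSD = "numeric", noiseSD = "numeric",
                   replicateSD = "numeric"))

setValidity("NoiseModel", function(object) {
    sds <- c(object@scatterGainSD, object@scatterOffsetSD, object@driftSD,
             object@noiseSD, object@replicateSD)
    if (any(sds < 0)) "all SDs must be >= 0" else TRUE
})

#' DesignSpec: concentration design of a mixture study
#'
#' @slot levels adulterant mass fractions in % w/w.
#' @slot replicates number of replicate preparations per level.
#' @slot adulterant adulterant label for every sample in the design.
#' @slot setLabel set membership assigned to every sample.
#' @export
setClass("DesignSpec",
    representation(levels = "numeric", replicates = "integer",
                   adulterant = "character", setLabel = "character"))

setValidity("DesignSpec", function(object) {
    msg <- character()
    if (any(object@levels < 0) || any(object@levels > 100))
        msg <- c(msg, "levels must lie in [0, 100]")
    if (object@replicates < 1L) msg <- c(msg, "replicates must be >= 1")
    if (!object@adulterant %in% .ADULTERANTS)
        msg <- c(msg, "unknown adulterant")
    if (!object@setLabel %in% .SET_LABELS)
        msg <- c(msg, "unknown set label")
    if (length(msg)) msg else TRUE
})

#' PreprocessScheme: an ordered spectral preprocessing pipeline
#'
#' @slot schemeId unique identifier within a catalogue.
#' @slot steps ordered list; each element is `list(name = , params = list())`
#'   with `name` among `sg_smooth`, `sg_derivative`, `snv`, `msc`, `emsc`,
#'   `isc`, `eisc`, `detrend`, `unit_variance`.
#' @export
setClass("PreprocessScheme",
    representation(schemeId = "character", steps = "list"))

.STEP_NAMES <- c("sg_smooth", "sg_derivative", "snv", "msc", "emsc",
                 "isc", "eisc", "detrend", "unit_variance")

setValidity("PreprocessScheme", function(object) {
    nm <- vapply(object@steps, function(s) s$name, character(1))
    if (!all(nm %in% .STEP_NAMES))
        paste("unknown step name(s):", paste(setdiff(nm, .STEP_NAMES), collapse = ", "))
    else TRUE
})

#' FittedScheme: a preprocessing scheme with training-learned parameters
#'
#' Holds, per step, the parameters learned on the calibration (training)
#' spectra — the MSC/EMSC/ISC/EISC reference spectrum and unit-variance column
#' scales — so that exactly the same transform is replayed on any other set.
#'
#' @slot scheme the [PreprocessScheme-class] that was fitted.
#' @slot learned list parallel to `scheme@steps`; `NULL` for stateless steps.
#' @slot wavelengths wavelength grid the scheme was fitted on.
#' @export
setClass("FittedScheme",
    representation(scheme = "PreprocessScheme", learned = "list",
                   wavelengths = "numeric"))

#' PCAModel: principal component decomposition of a spectra matrix
#'
#' @slot center mean spectrum used for column centering.
#' @slot loadings wavelengths-by-components orthonormal loading matrix.
#' @slot scores samples-by-components score matrix.
#' @slot explainedVariance per-component variance (score variance, n-1).
#' @slot varPercent per-component percentage of total variance.
#' @export
setClass("PCAModel",
    representation(center = "numeric", loadings = "matrix", scores = "matrix",
                   explainedVariance = "numeric", varPercent = "numeric"))

setValidity("PCAModel", function(object) {
    msg <- character()
    G <- crossprod(object@loadings)
    if (max(abs(G - diag(ncol(G)))) > 1e-8)
        msg <- c(msg, "loadings are not orthonormal")
    if (is.unsorted(rev(object@explainedVariance)))
        msg <- c(msg, "explained variance must be non-increasing")
    if (length(msg)) msg else TRUE
})

#' LatentRegressionModel: PCR or PLSR calibration model
#'
#' A linear calibration model relating (preprocessed) spectra to adulterant
#' concentration through `f` latent variables. `beta` is the regression
#' vector folded back to wavelength space, so prediction is
#' `X %*% beta + intercept`.
#'
#' @slot kind `"pcr"` or `"plsr"`.
#' @slot f number of latent variables.
#' @slot centerX training mean spectrum.
#' @slot centerY training mean response.
#' @slot beta regression vector (one entry per wavelength).
#' @slot intercept scalar intercept.
#' @slot fitted fitted values on the training data.
#' @export
setClass("LatentRegressionModel",
    representation(kind = "character", f = "integer", centerX = "numeric",
                   centerY = "numeric", beta = "numeric", intercept = "numeric",
                   fitted = "numeric"))

setValidity("LatentRegressionModel", function(object) {
    msg <- character()
    if (!object@kind %in% c("pcr", "plsr")) msg <- c(msg, "kind must be pcr or plsr")
    if (object@f < 1L) msg <- c(msg, "f must be >= 1")
    if (length(msg)) msg else TRUE
})

#' DiscriminantModel: two-class PLS-DA model
#'
#' PLSR fitted on a class code y in \{-1, +1\}; hard decision rule
#' `score >= threshold -> +1` (ties assigned to +1).
#'
#' @slot base the underlying [LatentRegressionModel-class].
#' @slot threshold decision threshold on the continuous score (default 0).
#' @slot classMap named character; names `"-1"`, `"+1"` mapped to class labels.
#' @export
setClass("DiscriminantModel",
    representation(base = "LatentRegressionModel", threshold = "numeric",
                   classMap = "character"))

#' OneClassModel: one-class PLS acceptance model
#'
#' Latent decomposition of the target-class spectra (uncentered X against a
#' constant unit response) with two soft acceptance rules: a Mahalanobis
#' distance in score space against an F-based Hotelling-type limit, and a
#' squared reconstruction residual against a Box scaled-chi-square limit.
#' A sample is accepted only if both statistics fall below their thresholds.
#'
#' @slot weights wavelength-by-component PLS weight matrix W.
#' @slot projection wavelength-by-component matrix R = W (P'W)^-1 mapping
#'   spectra to scores.
#' @slot loadings wavelength-by-component X-loading matrix P.
#' @slot scoreMeans,scoreSD training score means and SDs per component.
#' @slot dCrit score-distance threshold.
#' @slot qCrit residual threshold.
#' @slot alpha nominal false-rejection rate (split alpha/2 per rule).
#' @slot f number of latent variables.
#' @export
setClass("OneClassModel",
    representation(weights = "matrix", projection = "matrix",
                   loadings = "matrix", scoreMeans = "numeric",
                   scoreSD = "numeric", dCrit = "numeric", qCrit = "numeric",
                   alpha = "numeric", f = "integer"))

setValidity("OneClassModel", function(object) {
    msg <- character()
    if (object@dCrit <= 0) msg <- c(msg, "dCrit must be > 0")
    if (object@qCrit <= 0) msg <- c(msg, "qCrit must be > 0")
    if (any(object@scoreSD <= 0)) msg <- c(msg, "degenerate score variance")
    if (length(msg)) msg else TRUE
})

#' MCReport: Monte Carlo figures of merit with uncertainties
#'
#' Mean and standard deviation (n-1), across Monte Carlo iterations, of the
#' correct classification rate, sensitivity and specificity on the training
#' draw, the internal test remainder and the fixed external validation set.
#' All values in percent.
#'
#' @slot mean,sd 3x3 matrices, rows = metrics (CCR, sensitivity, specificity),
#'   columns = sets (training, test, validation).
#' @slot iterations number of Monte Carlo iterations.
#' @slot f model complexity used.
#' @slot positiveClass label coded +1 (the "positive" class for
#'   sensitivity).
#' @slot degenerate TRUE when iterations == 1 (SDs reported as 0).
#' @export
setClass("MCReport",
    representation(mean = "matrix", sd = "matrix", iterations = "integer",
                   f = "integer", positiveClass = "character",
                   degenerate = "logical"))
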