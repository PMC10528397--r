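# Internal helpers shared across modules.

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    eval.parent(substitute(expr))
}

# Deterministic 32-bit substream seed derived from a master seed, so adding a
# simulation stage never perturbs the draws of earlier stages.
substreamSeed <- function(seed, index) {
    (abs(as.numeric(seed)) * 69069 + 104729 * as.numeric(index)) %% 2147483587
}

# Coerce a SpectraSet or numeric matrix to the samples-by-wavelengths matrix.
asSpectraMatrix <- function(x) {
    if (is(x, "SpectraSet")) spectra(x)
    else if (is.matrix(x)) x
    else if (is.numeric(x)) matrix(x, nrow = 1)
    else stop("expected a SpectraSet, matrix or numeric vector")
}

# Replace the absorbance matrix of a SpectraSet (same shape), or return the
# matrix unchanged when the input was a matrix.
replaceSpectra <- function(x, M) {
    if (is(x, "SpectraSet")) {
        A <- t(M)
        dimnames(A) <- dimnames(SummarizedExperiment::assay(x, "absorbance"))
        SummarizedExperiment::assay(x, "absorbance") <- A
        x
    } else M
}

# Response vector for model fitting: the adulterant mass fraction.
responseOf <- function(x, y = NULL) {
    if (!is.null(y)) return(as.numeric(y))
    if (is(x, "SpectraSet")) return(sampleMeta(x)$fraction)
    stop("y must be supplied when x is a plain matrix")
}

# Column SD with the n-1 denominator.
colSds <- function(M) {
    n <- nrow(M)
    if (n < 2) stop("need at least 2 rows to compute column SDs")
    mu <- colMeans(M)
    sqrt(colSums(sweep(M, 2, mu)^2) / (n - 1))
}
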