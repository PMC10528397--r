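Package: garlicNIR
Title: Chemometric Quantification and Detection of Powdered-Garlic
    Adulteration from FT-NIR Spectra
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multivariate calibration and classification toolkit for
    detecting and quantifying powder adulterants (corn flour, corn starch)
    in ground garlic from Fourier-transform near-infrared absorbance
    spectra. Provides an S4 container for spectra with sample metadata, a
    catalogue of spectral preprocessing methods (Savitzky-Golay smoothing
    and derivatives, SNV, MSC, EMSC, ISC, EISC, detrending, unit-variance
    scaling) with strict train/apply separation, principal component
    regression and NIPALS partial least squares regression with exhaustive
    preprocessing-by-complexity model search, PLS-DA discrimination with
    Monte Carlo uncertainty estimation, one-class PLS adulterant-type
    detection with score-distance and residual acceptance rules, and a
    synthetic binary-mixture spectra generator emulating the experimental
    design so the full pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    signal,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'SpectraSet.R'
    'utils.R'
    'latent.R'
    'classify.R'
    'preprocess.R'
    'validation.R'
    'search.R'
    'synthetic.R'
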