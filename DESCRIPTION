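Package: dccabci
Title: Detrended Cross-Correlation Covariance Features for Riemannian
    Motor-Imagery Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decodes two-class motor-imagery EEG with a minimum-distance-to-mean
    classifier on the manifold of symmetric positive-definite matrices, using
    detrended cross-correlation analysis (DCCA) matrices in place of sample
    covariance matrices. Provides batch and constant-cost streaming (rtDCCA)
    estimation of pairwise detrended covariances, detrended fluctuation
    analysis (DFA) and the detrended cross-correlation coefficient (DCCC),
    affine-invariant Riemannian geometry (geodesics, distances, Karcher
    means), offline and causally adaptive recentering of covariance features,
    a CSP+LDA baseline decoder, Butterworth filtering and epoching, an online
    trial protocol with exponentially smoothed evidence accumulation,
    command-delivery and sample-wise performance metrics with binomial chance
    levels, group-level statistics, post-hoc fractal connectivity and DFA
    topography analyses, a synthetic motor-imagery session generator
    (fractional Gaussian noise background, contralateral variance reduction,
    polynomial drifts, between-session covariance shifts), and minimal
    EDF/EDF+ input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    signal,
    nortest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
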