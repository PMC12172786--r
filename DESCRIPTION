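Package: emosig
Title: Neural Signature Expression Scoring and Mega-Analysis of Emotional Reactivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Applies multivariate neural signature weight maps (such as the
    Picture-Induced Negative Emotion Signature and discrete-emotion patterns)
    to first-level fMRI beta images by voxelwise dot-product scoring, and
    analyses the resulting reactivity scores: run-level reliability
    (Cronbach's alpha, inter-run correlations), forced-choice accuracy,
    single-study condition and group effects with Cohen's d and
    noncentral-t confidence intervals, individual-participant-data
    mega-analysis with run-specific standardization and a restricted
    maximum likelihood random-intercept model, and directional
    default-prior (JZS) Bayes factors computed by adaptive quadrature.
    Includes a synthetic beta-map generator with known ground truth for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    jsonlite,
    withr
Config/testthat/edition: 3
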