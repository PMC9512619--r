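Package: fidgetr
Title: Detection and Neural Correlates of Fidget Behavior in Head-Fixed Mice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, simulation-backed analysis pipeline for studying
    fidgets - brief, stereotyped startle-like body movements of head-fixed
    mice - and their correlates in visual cortical calcium imaging. Provides
    a synthetic-session generator with controllable ground truth (behavioral
    video, frame labels, dF/F traces, drifting-grating stimulus tables,
    running speed); a fidget detector built from histogram-of-oriented-
    gradients features, PCA and a radial-basis-function support vector
    machine; dense Farneback optical flow for fidget magnitude; event-aligned
    z-scoring and k-means++ clustering with gap-statistic model selection
    into four response types; UMAP / gradient-boosted-tree decodability tests
    of cortical area, layer and Cre-line with shuffled-label baselines; and
    fidget-versus-running visual-response modulation analysis with Cohen's d
    and Benjamini-Hochberg-corrected per-cell tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    uwot,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
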