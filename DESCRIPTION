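Package: dargspot
Title: Signature Voting, Recovery-AUC Scoring and Spatial Calling of
    Disease-Associated Radial Glia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies disease-associated radial-glia-like (DARG) cells and
    spots in single-cell and spatial transcriptomic count data. Implements
    k-of-n gene-signature voting with per-gene expression thresholds,
    rank-based signature-recovery AUC scoring in which zero-count genes are
    excluded from per-observation rankings, a permutation background null
    built from random gene sets of matched size, dual-criterion (AUC plus
    vote-count) DARG-high spot calling with niche and patient-level
    summaries, quantile-binned Welch t-tests, and size-penalized Fisher
    exact matching of gene modules between datasets with Benjamini-Hochberg
    correction. Includes negative-binomial simulators for count matrices,
    concentric lesion layouts and module collections with planted ground
    truth, so the full pipeline can be exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
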