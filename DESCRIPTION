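Package: icaref
Title: Stable One-Unit Independent Component Analysis with Reference
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Constrained independent component analysis with a reference
    signal (ICA-R) for biomedical signal processing, e.g. extracting the
    fetal electrocardiogram from maternal abdominal recordings or removing
    artifacts from EEG. Implements a stabilized fast one-unit extractor
    that maximizes an approximate negentropy contrast under an inequality
    closeness constraint handled by an augmented Lagrangian multiplier,
    detects impending misconvergence (secondary rise of the inequality
    multiplier, negative Newton curvature) and restarts from
    Gram-Schmidt-orthogonal initial vectors. Includes the legacy one-unit
    ICA-R learning rules as baselines, reference deflation and direct
    channel references, threshold-widening extraction, complete recovery
    of all independent components with a nonconvergence stopping rule,
    synthetic fixture generators for sub- and super-Gaussian sources, and
    a benchmark harness for misconvergence statistics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, pracma, jsonlite
Suggests: testthat (>= 3.0.0), yaml, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
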