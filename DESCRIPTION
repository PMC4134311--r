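Package: sogica
Title: Group Spatial ICA Comparison of Intrinsic Connectivity Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Compares intrinsic connectivity networks between two groups
    from 4-D fMRI time series: per-subject spatial FastICA by deflation
    with tanh contrast, template-based network identification,
    self-organizing clustering of independent components across subjects,
    voxel-wise one-way ANOVA with Monte Carlo cluster-extent correction,
    and reduction of concurrently recorded physiological traces
    (tumescence, cardiac, respiratory) to group statistics. Includes a
    synthetic two-group cohort generator with planted spatial networks,
    node-loading group effects, nuisance signals and physiological traces
    so the full pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
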