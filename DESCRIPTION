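Package: renaldce
Title: Patlak Perfusion Analysis of Renal Dynamic Contrast-Enhanced MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tracer-kinetic analysis of dynamic contrast-enhanced (DCE) MRI of
    the kidney: forward compartment models (Patlak, extended Tofts,
    two-compartment uptake and exchange), voxel-wise Patlak fitting with
    model selection by the Akaike information criterion, arterial input
    function extraction, rigid motion correction, ROI aggregation, exact
    small-sample nonparametric group comparison (Mann-Whitney U, Wilcoxon
    signed-rank, rank-biserial effect sizes, Hodges-Lehmann shift estimates
    with exact confidence intervals), and a synthetic phantom generator for
    end-to-end validation of the whole pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    lhs,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
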