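Package: xciescape
Title: Allele-Specific Quantification of X-Inactivation Escape and
    Transgene Boundary Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify X-chromosome inactivation (XCI) escape and to
    map X-linked BAC transgene content from allele-specific measurements in
    hybrid (129 x CAST) mouse cells. Turns quantitative primer-extension peak
    heights into normalized (129+BAC)/CAST dosage ratios, calls transgene
    presence and copy number per SNP, and localizes truncation breakpoints to
    a bracketing SNP interval. Estimates inactive-X expression as a fraction
    of active-X expression, including a closed-form shared-allele
    deconvolution for transgenes indistinguishable from the active-X allele
    and a detection-floor censoring rule. Models RNA FISH scoring categories
    under competing XCI hypotheses given strain-driven XCI skewing and
    classifies observed nucleus counts by chi-square goodness of fit.
    Analyzes 3D DNA FISH probe associations with nuclear-area-normalized
    distances, cumulative frequency curves, and two-sample
    Kolmogorov-Smirnov comparisons. A fully parameterized forward simulator
    generates every input table so the whole pipeline is testable without
    microscopy or sequencer data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
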