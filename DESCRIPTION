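Package: neurocultr
Title: Quantification of Neuronal Network Development in Cultured Cortical Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for quantifying in vitro neuronal network development
    and morphology in two-genotype (e.g. wild-type versus haploinsufficient)
    cortical cultures. Implements multielectrode-array spike detection at a
    robust noise-scaled threshold, network-burst detection, a chance-corrected
    synchrony index, local field potential extraction with Welch band-power
    ratio timecourses, calcium transient detection with a surrogate-calibrated
    correlated-firing ratio, Sholl and synaptic-puncta morphometry on SWC
    reconstructions and two-channel images, and the group-comparison statistics
    layer (pooled/Welch t from raw data or published summary statistics,
    two-way ANOVA, exact Mann-Whitney U, Benjamini-Hochberg FDR). A synthetic
    cohort generator with known ground truth makes every stage testable at
    desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    zoo
Suggests:
    car,
    optparse,
    testthat (>= 3.0.0),
    tiff,
    yaml
Config/testthat/edition: 3
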