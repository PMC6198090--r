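Package: topodens
Title: Neuronal Topographic Density Mapping and Micro-ROI Statistics
Version: 0.1.0
Authors@R:
    person("topodens", "developers", email = "topodens@example.org",
           role = c("aut", "cre"))
Description: Builds registered neuron-density bin matrices from per-subject
    marker coordinates and anatomical contours, renders mean, coefficient-of-
    variance and difference heat maps, and detects statistically significant
    micro-regions of interest (MROIs) by mass-univariate ANOVA with
    Benjamini-Hochberg false-discovery-rate control. Includes Feret-length
    section-alignment quality control, principal component and multiple
    discriminant analysis of regional densities, a synthetic cohort generator
    with known ground truth, plain-text readers for Neurolucida-style ASCII
    marker and contour exports, and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
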