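Package: borealsens
Title: Lagged Climate Sensitivity of Circumboreal Forest Productivity Indices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds standard tree-ring width index chronologies from raw ring
    widths (frequency-cutoff smoothing-spline detrending, ratio indices, EPS
    screening), harmonizes point chronologies and gridded greenness/NPP fields
    onto a coarse consistent latitude-longitude grid, forms latitude-dependent
    summer climate composites, and classifies per-grid-cell lagged (current
    versus previous summer) Pearson correlations of forest productivity
    indices with temperature and precipitation. Includes a synthetic-data
    generator with known lag structure so every pipeline stage has a
    parameter-recovery test, plus summary tables, histograms and kernel
    density summaries of correlation fields.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ncdf4
Config/testthat/edition: 3
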