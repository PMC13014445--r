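Package: xvgplot
Title: Batch Publication-Quality Figures from Grace 'xvg' and Delimited
    Simulation Output
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reads the Grace-dialect 'xvg' files written by GROMACS analysis
    tools and delimited text files (including OpenMM-style CSV energy
    reports) into a common document model, transforms and summarizes the
    data (residual plots, histograms, RMSD and squared-correlation
    statistics, 2D probability densities, Gibbs free-energy landscapes by
    Boltzmann inversion, kernel density estimates), and renders single- and
    multi-panel figures to PDF or PNG headlessly or on screen.  A
    command-line front end supports batch figure generation; the same code
    path is available as a programmatic API.  A seeded fixture generator
    produces realistic synthetic inputs for testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    patchwork,
    MASS,
    stats,
    grDevices,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
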