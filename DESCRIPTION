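Package: damfretr
Title: Nucleation-Barrier Detection and Saturation-Concentration Estimation
    from DAmFRET Flow Cytometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for Distributed Amphifluoric FRET (DAmFRET)
    single-cell flow cytometry of protein self-assembly. Ingests per-cell
    event tables, applies logicle transforms and scatter/expression gates,
    builds 64-bin logarithmic AmFRET profiles with a 99th-percentile
    monomer-control gate, classifies concentration-dependent assembly as
    continuous or discontinuous using bootstrapped spline change-point
    detection and Hartigan's dip test, estimates saturation concentrations
    (C50) and supersaturability by bounded Weibull (stretched-exponential)
    fitting with Monte-Carlo errors, calls nucleating ("seeding")
    interactions in all-by-all screens via per-batch standardization and
    IQR outlier degrees, classifies assembly morphology (diffuse, punctate,
    fibrillar) from confocal images, and provides the downstream network
    and correlation statistics. A synthetic-data module generates event
    tables, screens, and images with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    signal,
    minpack.lm,
    igraph,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    quadprog,
    tiff,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
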