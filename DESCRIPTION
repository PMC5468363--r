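Package: sdpipe
Title: Streaming SD-File Pipelines, Scaffold Tagging, Property
    Calculation and Conformational Strain Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A command-line style toolkit for structure-data (SD) file
    workflows in drug discovery. Provides a streaming, order-preserving
    reader and writer for V2000 SD files and tab-delimited tables;
    ordered-SMARTS series tagging; dependency-resolved physicochemical
    property calculation driven by an XML calculator registry;
    composable record-stream pipelines that compile to executable UNIX
    pipes and parallelize over workers; and a conformational
    strain-energy protocol (flat-bottom constrained minima, torsion
    enumeration with polar-hydrogen sampling, Pareto-optimal conformer
    retention, symmetry-corrected alignment, and strain-at-threshold
    statistics) built on a compact molecular-mechanics force field with
    analytic gradients.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    parallel,
    xml2,
    igraph,
    ChemmineR,
    ChemmineOB,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
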