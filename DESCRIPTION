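Package: auxoDesign
Title: Design of Auxotrophy-Dependent Microbial Biosensors and
    Growth-Coupled Production Strains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constraint-based design of microbial biosensors and
    chemical-producing strains on genome-scale (or toy) metabolic network
    models. Implements flux balance analysis, a bi-level mixed-integer
    formulation that finds gene-knockout sets making growth strictly
    dependent on a sensed chemical (ultra-auxotrophy), enumeration of
    alternative designs via integer cuts, spent-medium yield-sensitivity
    classification, and the OptKnock / RobustKnock family of strain-design
    programs including proxy-metabolite variants that couple production of
    a target chemical to secretion of a detectable proxy. Models are read
    from SBML or COBRA-style JSON; all optimization is solved with the GLPK
    command-line solver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, Matrix, jsonlite, xml2, yaml
Suggests: testthat (>= 3.0.0), optparse
SystemRequirements: GLPK (the glpsol executable must be on the PATH)
Config/testthat/edition: 3
biocViews: Software, Metabolomics, NetworkInference, SystemsBiology
RoxygenNote: 7.3.3
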