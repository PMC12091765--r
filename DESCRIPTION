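Package: necindex
Title: Neighborhood Eccentricity Topological Indices and QSPR Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes neighborhood-eccentricity-based topological indices of
    hydrogen-depleted molecular graphs through the bivariate NEC polynomial and
    an exact operator calculus (derivative, integral-average, exponent-shift and
    diagonalisation operators over sparse Laurent polynomials with exact
    rational coefficients). Every index is computed twice, by direct edge-class
    summation and by the operator route, with enforced exact agreement. Ships
    edge-partition and molecular-graph fixtures for eight antiviral and
    repurposed drugs together with their physico-chemical property table, and
    fits linear and cubic quantitative structure-property relationship (QSPR)
    regressions of eight properties on eight indices, including correlation
    matrices, significance calls and actual-versus-predicted tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ChemmineR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
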