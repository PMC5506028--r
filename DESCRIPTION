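Package: tissuefail
Title: Interdependent Cell Failure and Mortality Analysis in Engineered Tissue Constructs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic agent-based simulation of cascading cell failure in
    hydrogel tissue constructs ("aging in a dish"), with intrinsic damage,
    threshold cascades and cooperative secreted-factor support; a synthetic
    measurement emulator of daily dead-cell z-stack imaging; the dead-cell
    counting pipeline (stereological scaling, cumulative live-cell bookkeeping,
    live-percentage series, tissue lifetime); mortality-rate estimation with an
    exponential (non-interacting) null, m(n) trend classification and
    normalized-time curves; nearest-neighbor distance analysis of the cell
    point pattern; and scenario orchestration for density sweeps, oxidative
    stress and conditioned-media transfer experiments discriminating between
    production-loss and reception-loss hypotheses of cellular aging.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
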