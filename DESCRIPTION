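Package: rankdyn
Title: Displacement-Replacement Dynamics of Ranking Lists
Version: 0.1.0
Authors@R:
    person("rankdyn", "maintainers", email = "rankdyn@example.org",
           role = c("aut", "cre"))
Description: Tools for the statistical analysis of longitudinal ranking
    lists (top-N0 lists observed at T time points) and for a minimal
    stochastic model of their dynamics in which elements either jump to a
    uniformly random rank (displacement, a Levy walk in rank space) or are
    replaced by brand-new elements (replacement, a birth-death event).
    Provides empirical rank observables (flux, turnover, per-rank change
    probability, displacement distributions), a fast simulator of the
    two-parameter model, closed-form theory (Levy term plus a
    Wright-Fisher-type degenerate diffusion kernel), inversion of the mean
    flux and mean turnover-rate equations to estimate the displacement and
    replacement rates, rescaling onto the universal curve tau_r * nu_r = 1,
    regime classification (Levy / diffusion / replacement), subsampling and
    parametric-bootstrap analyses, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
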