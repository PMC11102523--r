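Package: viralsir
Title: Sharing and Advertising Dynamics of Viral Videos via an SIR Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for an SIR-type compartmental model of viral-video
    spread in which susceptible individuals become viewers either through
    person-to-person sharing or through an advertising forcing term
    gamma*N^2/(N+I). Provides deterministic integration of the full,
    reduced and fraction-form systems, closed-form interior equilibria
    with stability certificates, a lineage-tracking agent-based simulator
    that attributes every viewer to a sharing or an advertising root,
    cumulative sharing/advertising conversion integrals, and least-squares
    calibration of the model to daily view-count series by Nelder-Mead
    search, together with a synthetic view-series generator for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
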