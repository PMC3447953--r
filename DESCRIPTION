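Package: scnsim
Title: Simulation of Seasonal Network Plasticity in the Suprachiasmatic Nucleus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates the mammalian circadian pacemaker (the suprachiasmatic
    nucleus, SCN) as a network of heterogeneous single-cell oscillators coupled
    on a two-region graph. Dorsomedial cells form a random geometric graph of
    short-range connections; long-range connections are added with a tunable
    probability delta that encodes seasonal (summer/winter) network plasticity.
    Provides spiking Poincare and Goodwin gene-circuit single-cell backends,
    square-wave photic forcing restricted to the ventrolateral region, and the
    accompanying analyses: mean-field activity width and amplitude, pairwise
    correlation matrices, peak-phase distributions, finite and infinitesimal
    (adjoint) phase response curves, Arnold-tongue entrainment scans,
    small-world metrics (efficiency, clustering, their product), and
    singular-value spectra of the local-mean-field graph Laplacian.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    igraph,
    Matrix,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
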