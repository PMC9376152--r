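Package: crtransients
Title: Long Transients in a Pulsed Consumer-Resource Model with Group Defense
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for a discrete-time consumer-resource model in which the
    resource exhibits group defense (a unimodal Type IV Holling functional
    response) and both populations recruit in discrete reproductive pulses.
    Provides numerically stable (log-space) iteration of the pulse-to-pulse
    map, conversion from the dimensional impulsive formulation to the
    nondimensional map, a catalog of fixed points with Jacobian-based
    stability classification and the transcritical bifurcation value of the
    consumer conversion intensity, and estimators for long-transient
    durations: crawl-by times near resource extinction and near carrying
    capacity, ghost-attractor escape times, and a power-law fit of transient
    time against distance to the bifurcation. Includes one-command runners
    for the standard simulation experiments and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
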