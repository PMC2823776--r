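Package: endoabm
Title: Agent-Based Simulation of Endotoxin-Induced Acute Inflammation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Stochastic, spatially explicit agent-based model of the acute
    inflammatory response of human blood leukocytes to endotoxin.  Composite
    macrophage agents (membrane ring, nucleus, embedded TLR4/TNFR/IL-4
    receptors, intracellular NF-kB/IkBa/IKK signaling agents) and T-helper
    cells interact with mobile molecule agents (LPS, TNF-a, IL-12, IL-4,
    IKK-inhibitor) on a toroidal patch world under published stochastic
    interaction rules.  Ships the seven published dosing scenarios
    (self-limited, high-dose, persistent infection, endotoxin tolerance,
    lethal potentiation, two-hit, IKK-inhibitor rescue), a seeded replicate
    runner with outcome classification (self-limited versus unconstrained
    inflammation), snapshots for resumable runs, and a pattern-oriented
    parameter-sweep calibration harness.  The tick loop is implemented in
    C++ via Rcpp.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
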