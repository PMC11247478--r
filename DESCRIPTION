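Package: reaxtrack
Title: Reaction Product and Pathway Tracking from Reactive MD Bond Orders
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Post-processing toolkit for reactive molecular dynamics (ReaxFF)
    bond-order trajectories. Reads LAMMPS reaxff/bonds dumps, identifies
    chemical species per frame as connected components of the bond-order graph
    above a cutoff, selects the cutoff from a distinct-species sweep, filters
    short-lived flicker species by lifetime, ranks reaction products by
    trailing-window prevalence, tracks labeled template bonds to detect
    committed dissociation/formation/single-double events, reconstructs
    dominant reaction pathways per product, and fits degradation-onset
    temperatures from temperature-ramp runs. Ships a ground-truth-annotated
    synthetic trajectory generator emulating thermo-oxidation of modified
    lignin model compounds so every analysis is testable without running MD.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
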