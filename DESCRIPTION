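Package: ringmotor
Title: Potential-Switching Coarse-Grained Simulation of Ring-Motor Helicase
    Translocation, DNA Unwinding and Nucleosome Navigation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained Langevin-dynamics simulation of a hexameric
    ring-motor helicase translocating on single-stranded DNA by periodic
    switching among four DNA-binding states, unwinding duplex DNA at a
    Y-fork, and navigating a nucleosome. Provides toy structure generators
    (ring, ssDNA, Y-fork, nucleosome, accessory factors), a switchable
    force field with coarse-grained hydrogen-bond wells and Debye-Hueckel
    electrostatics, a BAOAB Langevin integrator with a state-switching
    scheduler, the full set of trajectory metrics (per-transition step
    sizes, anchor identity, unwound base pairs, pore clogging, nucleosome
    unwrapping extent, lagging-strand capture, contact probabilities,
    occupancy densities), and a seeded experiment registry with replicate
    aggregation and Wilcoxon-Mann-Whitney condition comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
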