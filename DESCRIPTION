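Package: qstox
Title: Quantitative Systems Toxicology Models of Myelosuppression and
    Intestinal Epithelial Injury
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulators and analysis tools for two quantitative systems
    toxicology models of oncology drug adverse effects. The first is the
    classical five-compartment transit model of chemotherapy-induced
    myelosuppression (proliferating progenitors, a maturation chain,
    circulating neutrophils, and a feedback exponent gamma), with
    fractional-kill treatment events, CTCAE neutropenia grading, and a
    linear-stability toolkit that locates the Hopf bifurcation in gamma.
    The second is an agent-based cylindrical-lattice model of the small
    intestinal crypt feeding a villus, used to quantify how the position
    of a cycle-arrest injury within the transit-amplifying compartment
    determines recovery time and villus integrity. Includes a scenario
    generator for the standard treatment schedules and injury
    specifications, and report writers with run manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
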