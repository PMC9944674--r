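Package: ocupbpk
Title: Ocular PBPK Simulation and Rabbit-to-Human Exposure Extrapolation
    for Topical Ophthalmic Solutions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Physiologically based pharmacokinetic (PBPK) simulation of
    topically administered ophthalmic solutions. Implements a compartmental
    ocular absorption and transit model (tear-film drainage with volume
    capping, permeability-driven exchange between ocular tissues, linear
    melanin binding in pigmented tissues, systemic absorption routes)
    coupled to a reduced perfusion-limited whole-body PBPK model. Includes
    species physiology registries (albino and pigmented rabbit, human),
    drug parameter records for three fluoroquinolones, eye-drop dosing
    regimens, least-squares parameter estimation from sparse tissue
    concentration data, non-compartmental exposure metrics, synthetic
    study-data generation, and a rabbit-to-human extrapolation workflow in
    which only the physiology is exchanged between species.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
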