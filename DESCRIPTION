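Package: omusoc
Title: Intersexual Association Analysis for One-Male-Unit Multilevel Societies
Version: 0.1.0
Authors@R:
    person("Field", "Analyst", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to analyse female-male association patterns in multilevel
    primate societies organised around one-male units (OMUs), such as Guinea
    and hamadryas baboons. Builds weighted intersexual proximity networks from
    instantaneous scan samples, detects community structure (walktrap and a
    Potts-model simulated-annealing optimiser of Newman modularity), classifies
    males as primary, secondary or unaffiliated per female in fortnightly
    windows, computes dyad-level statistics (Hinde index of relationship
    maintenance, Friedman average-rank preference test with Nemenyi post hoc),
    and reconstructs female transfers between primary males and tenure lengths
    from ad libitum event streams. A companion simulator generates a synthetic
    multilevel society with a realistic scan- and focal-sampling observation
    process so every analysis stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
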