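Package: schizosim
Title: Discrete Event Simulation for Cost-Effectiveness of Antipsychotics in
    First-Episode Schizophrenia
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A patient-level discrete event simulation (DES) model for
    cost-utility analysis of antipsychotic treatment sequences in
    first-episode schizophrenia. Simulates relapse, remission, treatment
    discontinuation and switching, tardive dyskinesia, first coronary heart
    disease, stroke, diabetes and death for synthetic cohorts, converts
    trajectories into discounted quality-adjusted life years and costs from
    a health-service perspective, and ranks first-line antipsychotics by net
    monetary benefit across willingness-to-pay thresholds.  Includes
    probabilistic and deterministic sensitivity analyses, scenario analyses
    and a command-line interface.  Model parameters are supplied through a
    documented YAML schema; an illustrative (non-authoritative) UK parameter
    set is shipped.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
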