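Package: worksim
Title: Agent-Based Simulation of a No-Fault Workers' Compensation Scheme
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A discrete-time, agent-based simulator of injured-worker pathways
    through a no-fault workers' compensation scheme. Synthetic injured workers
    flow through triage (GP or emergency), claim lodgement, adjudication,
    disputes, funded treatment and return-to-work under configurable policy
    levers (acceptance rates, processing and treatment capacities, wage
    replacement, return-to-work promotion, occupational rehabilitation,
    advertising, benefit termination). The engine tracks per-worker health,
    trust, satisfaction and cost ledgers, emits per-time-step monitors, and a
    factorial experiment runner compares policy conditions with paired random
    seeds. Outputs are deliberately uncalibrated to any real scheme; the tool
    is for comparing the direction of policy effects, not their magnitude.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
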