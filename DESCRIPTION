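Package: lesionsim
Title: Spatio-Temporal Lesion and Recovery Simulation in Neural Network Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulators for studying how neural networks endure and recover from
    spatio-temporally structured damage. Provides a three-ring stochastic binary
    feed-forward network with a bounded Hebbian-like learning rule and a
    disability-dependent learning rate, a recurrent ring network with homeostatic
    structural plasticity (firing-rate-driven synapse creation and deletion), and
    a declarative lesion-scheduling layer (immediate, gradual, and resection
    injuries). An experiment layer quantifies the maximum amount of disability
    (MAoD) as a function of defect size and inter-removal time, with multi-seed
    grids, paired sign tests, reproducible seeding, and delimited trace and grid
    output with metadata sidecars.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
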