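Package: beetox
Title: Mechanistic Pesticide Exposure, Fate and Effect Simulation for
    Honeybee Colonies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A daily-time-step, cohort-based simulator of honeybee colony
    dynamics under pesticide exposure. Exposure of every cohort (foragers,
    in-hive bees, larvae and pupae) emerges from foraging behaviour on a
    patchy landscape, in-hive routing of nectar and pollen through a
    five-compartment honey-ripening chain, and dose-response toxicology
    parameterised directly from standard regulatory tests (acute oral,
    chronic oral, contact and larval endpoints). Includes a water-foraging
    module for cooling and honey-dilution demand, a semifield (tunnel)
    study scenario factory, paired control/treatment experiments with
    relative effect sizes, and tidy accessors and plots for all results.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
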