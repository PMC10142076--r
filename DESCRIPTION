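Package: nutrimission
Title: Gamified Food-Group Missions for Nutritional Behaviour Change
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An engine for food-group level dietary behaviour change built
    around a short food-frequency questionnaire (FFQ). It profiles users from
    FFQ responses, scores each food group against guideline serving ranges,
    assigns three-level adherence status, ranks and proposes gamified dietary
    missions through a forward-chaining rule engine, schedules motivational
    recommendations on a fixed cadence with dietary-preference filtering, and
    ships a seeded synthetic-user simulator so the whole intervention loop can
    be exercised end to end without real participants. All scoring tables,
    the mission catalogue and the rule base are data, not code, so dietary
    experts can revise them.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
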