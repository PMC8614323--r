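Package: peltbite
Title: Pelt Biting as an Indicator of Social and Heat Stress in Farmed Deer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study pelt biting, an agonistic-behaviour welfare
    indicator in farmed red deer. Provides the ordinal pelt-surface scoring
    scale with quartile subdivision, dominance-rank inference from agonistic
    interaction logs (Combi1 index with an I&SI linear ordering), the THIWS
    temperature-humidity-wind-solar heat-stress index, polynomial linear
    mixed models with crossed random intercepts (Satterthwaite degrees of
    freedom, Nakagawa marginal and conditional R2, backward elimination
    under marginality), and seeded synthetic-data generators that emulate a
    multi-year weekly monitoring programme so that every stage of the
    analysis can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
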