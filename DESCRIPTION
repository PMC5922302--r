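Package: somnet
Title: Self-Organising Map Networks for Health-System Indicator Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-support analytics for multi-dataset health-system key
    performance indicators (KPIs). Trains one hexagonal-grid self-organising
    map (SOM) per indicator dataset, links input maps to an output map through
    association weights learned from shared catchment areas, and supports
    robust outlier flagging with percentile winsorization, global and local
    pattern extraction via unit clusters, conditional input-driven and
    output-driven KPI estimation, and qualitative categorization of indicator
    values on a five-level 20 percent-interval scale. Includes a synthetic
    generator for three-region systems with planted structure, deterministic
    SVG renderings of component planes, label maps, star glyphs and weight
    fields, and a config-driven analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
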