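Package: capl2score
Title: Batch Scoring and Interpretation for the Canadian Assessment of
    Physical Literacy (Second Edition)
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes protocol scores, domain scores, an overall physical
    literacy score (0-100), age- and gender-specific interpretive categories,
    and domain completeness statuses from raw CAPL-2 (Canadian Assessment of
    Physical Literacy, second edition) field data. From the 60 required raw
    variables per child it derives 40 variables covering the physical
    competence, daily behaviour, motivation and confidence, and knowledge and
    understanding domains, with quiet validation (invalid values become NA
    rather than errors), missing-component reweighting of domain scores,
    pedometer wear-time validation with seeded step imputation, config-driven
    lookup tables, a demo-data simulator, tabular import and export, and
    interpretation-grouped bar plots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ggplot2,
    jsonlite,
    readxl,
    stats,
    tools,
    utils,
    zip
Suggests:
    haven,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
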