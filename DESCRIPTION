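Package: mpqs
Title: Meal Protein Quality Score for Meals, Recipes, and Dietary Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the Meal Protein Quality Score (MPQS), a composite
    measure of meal protein quantity and quality defined as the minimum,
    across essential amino acids, of digestibility-adjusted intake relative
    to a personalized per-meal requirement. Provides loaders for
    food-composition tables, recipes, and multi-day food records; per-meal
    and per-day scoring with the unidirectional methionine-to-cysteine
    top-up; cohort-level descriptive analyses (meal-moment summaries,
    plant-protein categories, limiting amino acid frequencies, per-person
    summaries); a seeded synthetic-data generator with contrasting food
    archetypes; and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
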