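Package: agroprior
Title: Fuzzy-Logic Prioritization of Plant Genetic Resources for Food and
    Agriculture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Ranks plant genetic resources for food and agriculture (PGRFA)
    for research and ex situ conservation investment using a four-pillar
    fuzzy inference system: geographic origin, vulnerability status,
    economic benefits, and food security importance. Per-species indicators
    (income per hectare, Lafay trade-balance index, municipality coverage,
    crop yield, micronutrient adequacy, nutrient-price ratios) are
    fuzzified with singleton and trapezoid membership functions on a
    0-100 universe, aggregated per pillar with weighted decision-index
    rules, and combined into a high/medium/low priority class with a crisp
    0-100 value obtained by centroid defuzzification of Gaussian output
    sets. Missing pillar data are imputed from taxonomic (gene pool) or
    FAO food-category donors with uncertainty tags, and a synthetic-data
    generator with planted ground-truth labels supports validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
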