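cfg <- default_config()

test_that("geographic classification follows the local > close > distant precedence", {
  expect_equal(classify_geographic("Andes"), "local")
  expect_equal(classify_geographic("Tropical South America"), "local")
  expect_equal(classify_geographic("Caribbean"), "close")
  expect_equal(classify_geographic(c("Australia", "Andes")), "local")
  expect_equal(classify_geographic(c("Europe", "Caribbean")), "close")
  expect_equal(classify_geographic("East Asia"), "distant")
  expect_equal(classify_geographic(character(0)), "undetermined")
  expect_error(classify_geographic("Atlantis"), "valid regions")
})

test_that("vulnerability merge: severest source wins, minor concern needs no threat", {
  expect_equal(classify_vulnerability("vulnerable", NA), "threatened")
  expect_equal(classify_vulnerability("endangered", "minor concern"),
               "threatened")
  expect_equal(classify_vulnerability(NA, "critically endangered"),
               "threatened")
  expect_equal(classify_vulnerability(NA, "least concern"), "minor_concern")
  expect_equal(classify_vulnerability("near threatened", NA), "minor_concern")
  expect_equal(classify_vulnerability(NA, NA), "not_evaluated")
  expect_error(classify_vulnerability("doomed", NA), "unknown national")
})

test_that("decision index: homogeneous economic label sets land in their class", {
  cov_map <- c(undetermined = "undetermined", low = "narrow",
               medium = "medium", high = "large")
  four <- function(l) c(lafay = l, yield = l, income = l,
                        coverage = unname(cov_map[l]))
  hi <- classify_economic(four("high"), cfg)
  expect_equal(hi$decision_index, 0.75)
  expect_equal(hi$label, "high")
  lo <- classify_economic(four("low"), cfg)
  expect_equal(lo$decision_index, 0.25)
  expect_equal(lo$label, "low")
  md <- classify_economic(four("medium"), cfg)
  expect_equal(md$decision_index, 0.5)
  expect_equal(md$label, "medium")
  ud <- classify_economic(c(lafay = "undetermined", yield = "undetermined",
                            income = "undetermined",
                            coverage = "undetermined"), cfg)
  expect_equal(ud$decision_index, 0)
  expect_equal(ud$label, "undetermined")
  # one missing variable pulls three highs down to medium
  mix <- classify_economic(c(lafay = "high", yield = "high", income = "high",
                             coverage = "undetermined"), cfg)
  expect_equal(mix$decision_index, 0.5625)
  expect_equal(mix$label, "medium")
  expect_error(classify_economic(four("gigantic"), cfg), "unknown label")
})

test_that("food security scores follow the published rule set", {
  f4 <- function(g, t, n, a) c(gov_list = g, traditional = t, nutrition = n,
                               affordability = a)
  hi <- classify_food_security(f4("included", "large", "high", "high"), cfg)
  expect_equal(hi$decision_index, 0.75)
  expect_equal(hi$label, "high")
  ud <- classify_food_security(
    f4("not_included", "narrow", "undetermined", "undetermined"), cfg)
  expect_equal(ud$decision_index, 0)
  expect_equal(ud$label, "undetermined")
  lo <- classify_food_security(f4("included", "medium", "low", "low"), cfg)
  expect_equal(lo$decision_index, 0.375)
  expect_equal(lo$label, "low")
  # medium food-security class opens at 0.45 (not 0.46)
  expect_equal(cfg$thresholds$food_security[["low_hi"]], 0.45)
  md <- classify_food_security(f4("not_included", "large", "medium", "high"),
                               cfg)
  expect_equal(md$decision_index, (0 + 3 + 2 + 3) / 16)
  expect_equal(md$label, "medium")
})

test_that("invert_affordability swaps the low and high affordability scores", {
  f4 <- c(gov_list = "not_included", traditional = "narrow",
          nutrition = "undetermined", affordability = "low")
  base <- classify_food_security(f4, cfg)
  cfg2 <- cfg
  cfg2$invert_affordability <- TRUE
  inv <- classify_food_security(f4, cfg2)
  expect_equal(base$decision_index, 1 / 16)
  expect_equal(inv$decision_index, 3 / 16)
})

test_that("rule tables enumerate 256 economic and 96 food combinations", {
  eco <- enumerate_rule_table("economic", cfg)
  expect_equal(nrow(eco), 256)
  expect_equal(nrow(unique(eco[, 1:4])), 256)
  fs <- enumerate_rule_table("food", cfg)
  expect_equal(nrow(fs), 96)
  expect_true(all(eco$class %in% c("undetermined", "low", "medium", "high")))
  expect_true(all(fs$class %in% c("undetermined", "low", "medium", "high")))
})

test_that("raising any single variable never lowers the output class", {
  cls_rank <- c(undetermined = 0, low = 1, medium = 2, high = 3)
  orders <- list(
    economic = list(lafay = c("undetermined", "low", "medium", "high"),
                    yield = c("undetermined", "low", "medium", "high"),
                    income = c("undetermined", "low", "medium", "high"),
                    coverage = c("undetermined", "narrow", "medium", "large")),
    food = list(gov_list = c("not_included", "included"),
                traditional = c("narrow", "medium", "large"),
                nutrition = c("undetermined", "low", "medium", "high"),
                affordability = c("undetermined", "low", "medium", "high")))
  for (pillar in names(orders)) {
    tab <- enumerate_rule_table(pillar, cfg)
    ord <- orders[[pillar]]
    key <- function(row) paste(row[names(ord)], collapse = "|")
    lut <- setNames(cls_rank[tab$class],
                    apply(tab[names(ord)], 1, paste, collapse = "|"))
    for (r in seq_len(nrow(tab))) {
      for (v in names(ord)) {
        pos <- match(tab[[v]][r], ord[[v]])
        if (pos == length(ord[[v]])) next
        up <- tab[r, names(ord), drop = FALSE]
        up[[v]] <- ord[[v]][pos + 1]
        expect_gte(lut[[key(up)]], lut[[key(tab[r, ])]])
      }
    }
  }
})

test_that("micronutrient blocks aggregate like a four-variable pillar", {
  all4 <- function(l) c(ca = l, fe = l, zn = l, energy = l)
  expect_equal(classify_micronutrient_block(all4("high"), "nutrition", cfg),
               "high")
  expect_equal(classify_micronutrient_block(all4("low"), "nutrition", cfg),
               "low")
  expect_equal(
    classify_micronutrient_block(all4("undetermined"), "affordability", cfg),
    "undetermined")
  expect_equal(classify_micronutrient_block(
    c(ca = "high", fe = "high", zn = "medium", energy = "medium"),
    "nutrition", cfg), "medium")
})
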