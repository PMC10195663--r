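cfg <- default_config()

test_that("complete species are never touched (idempotence, reliable tags)", {
  lab <- toy_labels(c("SP1", "SP2", "SP3"))
  sp <- toy_species(c("SP1", "SP2", "SP3"))
  res <- apply_imputation(lab, sp, cfg)
  expect_equal(res$labels, lab)
  expect_equal(nrow(res$audit), 0)
  expect_true(all(res$pillars$tag_economic == "reliable"))
  expect_true(all(res$pillars$tag_food_security == "reliable"))
})

test_that("gene-pool donor preferred, FAO-category fallback, NCB excluded", {
  ids <- c("SPmiss", "SPcong", "SPfao", "SPncb")
  lab <- toy_labels(ids)
  econ <- c("lafay", "yield", "income", "coverage")
  for (v in econ) lab[[v]][1] <- "undetermined"
  sp <- rbind(
    toy_species("SPmiss", genus = "Capsicum", fao = "vegetables and melons"),
    toy_species("SPcong", genus = "Capsicum", fao = "vegetables and melons"),
    toy_species("SPfao", genus = "Solanum", fao = "vegetables and melons"),
    toy_species("SPncb", group = "NCB", genus = "Capsicum",
                fao = "vegetables and melons"))
  pil <- classify_pillars(lab, cfg)
  # congener present: gene-pool path
  r <- resolve_donor("SPmiss", lab, pil, sp, "economic", cfg)
  expect_equal(r$path, "GP")
  expect_equal(r$donor, "SPcong")
  # no congener with data: fall back to the shared FAO category
  lab2 <- lab
  for (v in econ) lab2[[v]][2] <- "undetermined"
  pil2 <- classify_pillars(lab2, cfg)
  r2 <- resolve_donor("SPmiss", lab2, pil2, sp, "economic", cfg)
  expect_equal(r2$path, "PCG")
  expect_equal(r2$donor, "SPfao")
  # NCB species are never imputed even with a congener available
  lab3 <- toy_labels(ids)
  for (v in econ) lab3[[v]][4] <- "undetermined"
  pil3 <- classify_pillars(lab3, cfg)
  r3 <- resolve_donor("SPncb", lab3, pil3, sp, "economic", cfg)
  expect_equal(r3$path, "none")
})

test_that("among eligible donors the lowest decision index wins, ties by id", {
  ids <- c("SPmiss", "SPrich", "SPpoor", "SPpoor2")
  lab <- toy_labels(ids)
  econ <- c("lafay", "yield", "income", "coverage")
  for (v in econ) {
    lab[[v]][1] <- "undetermined"
    lab[[v]][3] <- if (v == "coverage") "narrow" else "low"
    lab[[v]][4] <- if (v == "coverage") "narrow" else "low"
  }
  sp <- toy_species(ids, genus = "Solanum")
  pil <- classify_pillars(lab, cfg)
  r <- resolve_donor("SPmiss", lab, pil, sp, "economic", cfg)
  expect_equal(r$path, "GP")
  expect_equal(r$donor, "SPpoor")  # 0.25 < 0.5; SPpoor < SPpoor2
})

test_that("a donor missing a variable leaves it missing in the recipient", {
  ids <- c("SPmiss", "SPdonor")
  lab <- toy_labels(ids)
  econ <- c("lafay", "yield", "income", "coverage")
  for (v in econ) lab[[v]][1] <- "undetermined"
  lab$income[2] <- "undetermined"   # donor lacks income too
  sp <- toy_species(ids, genus = "Musa")
  res <- apply_imputation(lab, sp, cfg)
  out <- res$labels[res$labels$species_id == "SPmiss", ]
  expect_equal(out$lafay, "medium")
  expect_equal(out$income, "undetermined")
  expect_equal(res$pillars$tag_economic[1], "GP")
})

test_that("a species whose own data score undetermined is not imputed", {
  # complete raw data, but every variable scores 0 or too low to decide
  ids <- c("SPweak", "SPstrong")
  lab <- toy_labels(ids, gov_list = c("not_included", "included"),
                    traditional = c("narrow", "large"),
                    nutrition = c("low", "high"),
                    affordability = c("low", "high"))
  sp <- toy_species(ids, genus = "Rubus")
  # raw data present for everything: missingness flags all FALSE
  miss <- data.frame(species_id = ids, lafay = FALSE, yield = FALSE,
                     income = FALSE, coverage = FALSE, gov_list = FALSE,
                     traditional = FALSE, nutrition = FALSE,
                     affordability = FALSE, geographic = FALSE)
  pil <- classify_pillars(lab, cfg)
  expect_equal(pil$food_security[1], "undetermined")  # ID = 2/16 < 0.25
  res <- apply_imputation(lab, sp, cfg, missing = miss)
  expect_equal(nrow(res$audit), 0)
  expect_equal(res$pillars$food_security[1], "undetermined")
  expect_equal(res$pillars$tag_food_security[1], "reliable")
})

test_that("geographic override pre-empts imputation", {
  ids <- c("SPnogeo", "SPdonor")
  lab <- toy_labels(ids, geographic = c("undetermined", "distant"))
  sp <- toy_species(ids, genus = "Solanum")
  cfg2 <- cfg
  cfg2$overrides$geographic <- c(SPnogeo = "close")
  res <- apply_imputation(lab, sp, cfg2)
  expect_equal(res$labels$geographic[1], "close")
  expect_equal(res$pillars$tag_geographic[1], "reliable")
  expect_equal(nrow(res$audit), 0)
  # without the override the distant congener is copied with a GP tag
  res2 <- apply_imputation(lab, sp, cfg)
  expect_equal(res2$labels$geographic[1], "distant")
  expect_equal(res2$pillars$tag_geographic[1], "GP")
})

test_that("tag accounting balances per pillar on a synthetic run", {
  syn <- generate_synthetic(n_species = 80, seed = 5)
  res <- run_pipeline(syn$dataset, syn$config)
  n <- nrow(res$pillars)
  for (tagcol in c("tag_geographic", "tag_economic", "tag_food_security")) {
    tags <- res$pillars[[tagcol]]
    expect_equal(sum(tags == "reliable") + sum(tags == "GP") +
                   sum(tags == "PCG"), n)
  }
  # every GP/PCG tag corresponds to an audit row and vice versa
  expect_equal(nrow(res$audit),
               sum(res$pillars$tag_economic != "reliable") +
                 sum(res$pillars$tag_food_security != "reliable") +
                 sum(res$pillars$tag_geographic != "reliable"))
})
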