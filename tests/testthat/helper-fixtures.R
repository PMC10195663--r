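# Shared helpers: a brute-force 1-D k-means oracle and a tiny hand-built
# dataset used across the io and imputation tests.

# exhaustive search over all order-preserving k-partitions of sorted data
brute_ckmeans <- function(x, k = 3L) {
  xs <- sort(x)
  n <- length(xs)
  sse <- function(v) sum((v - mean(v))^2)
  best <- Inf
  splits <- utils::combn(n - 1L, k - 1L)
  for (col in seq_len(ncol(splits))) {
    cut <- c(0L, splits[, col], n)
    tot <- 0
    for (q in seq_len(k)) tot <- tot + sse(xs[(cut[q] + 1L):cut[q + 1L]])
    if (tot < best) best <- tot
  }
  best
}

# minimal three-species dataset: one complete species per class archetype
toy_dataset <- function() {
  species <- data.frame(
    species_id = c("SP1", "SP2", "SP3"),
    taxon = c("Genus1 a", "Genus1 b", "Genus2 c"),
    group = c("BGVCOL", "BGVCOL", "NCB"),
    genus = c("Genus1", "Genus1", "Genus2"),
    fao_category = c("cereals", "cereals", "fruits and nuts"),
    stringsAsFactors = FALSE)
  regions <- data.frame(
    species_id = c("SP1", "SP2", "SP3"),
    region = c("Andes", "Caribbean", "Europe"),
    stringsAsFactors = FALSE)
  vulnerability <- data.frame(
    species_id = c("SP1", "SP2", "SP3"),
    national_category = c("endangered", "minor concern", NA),
    international_category = c(NA, NA, NA),
    stringsAsFactors = FALSE)
  economics <- data.frame(
    species_id = "SP1", year = 2017L, production_t = 1000,
    area_ha = 100, price_usd_t = 500, imports_t = 0, exports_t = 0,
    municipalities = 400, stringsAsFactors = FALSE)
  nutrition <- data.frame(
    species_id = "SP1", ca_mg_100g = 700, fe_mg_100g = 7.7,
    zn_mg_100g = 3.5, energy_kcal_100g = 945, consumption_g_day = 100,
    price_usd_100g = 0.5, stringsAsFactors = FALSE)
  government_list <- data.frame(species_id = c("SP1", "SP2", "SP3"),
                                included = c(TRUE, FALSE, FALSE),
                                stringsAsFactors = FALSE)
  traditional <- data.frame(species_id = c("SP1", "SP2", "SP3"),
                            n_regions = c(8, 2, 1),
                            stringsAsFactors = FALSE)
  structure(list(species = species, regions = regions,
                 vulnerability = vulnerability, economics = economics,
                 nutrition = nutrition, government_list = government_list,
                 traditional = traditional),
            class = c("agroprior_dataset", "list"))
}

# label table rows for imputation tests, defaulting to complete "medium" data
toy_labels <- function(ids, ...) {
  n <- length(ids)
  lab <- data.frame(
    species_id = ids,
    lafay = rep("medium", n), yield = rep("medium", n),
    income = rep("medium", n), coverage = rep("medium", n),
    gov_list = rep("included", n), traditional = rep("medium", n),
    nutrition = rep("medium", n), affordability = rep("medium", n),
    geographic = rep("local", n), vulnerability = rep("threatened", n),
    stringsAsFactors = FALSE)
  mods <- list(...)
  for (nm in names(mods)) lab[[nm]] <- mods[[nm]]
  lab
}

toy_species <- function(ids, group = "BGVCOL", genus = "Genus1",
                        fao = "cereals") {
  data.frame(species_id = ids, taxon = paste(genus, ids), group = group,
             genus = genus, fao_category = fao, stringsAsFactors = FALSE)
}
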