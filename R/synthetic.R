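# Synthetic fixture generator. Draws a target label per variable first, then
# samples the raw value from inside that label's membership plateau (inverted
# through the same normalization the pipeline applies, using fixed
# normalization bounds emitted in the accompanying config), so the planted
# ground truth is recovered deterministically. Missingness is applied
# afterwards, per pillar, to bank-conserved (BGVCOL) species.

.plateau_sample <- function(sets_spec, label, eps = 0.5, hard = FALSE,
                            cap = 100) {
  s <- Filter(function(x) x$label == label, sets_spec)[[1]]
  if (hard) {
    lo <- s$a; hi <- min(s$b, cap)
  } else {
    lo <- s$m; hi <- min(s$n, cap)
  }
  if (hi - lo < 2 * eps) return((lo + hi) / 2)
  stats::runif(1, lo + eps, hi - eps)
}

#' Generate a synthetic PGRFA dataset with planted ground truth
#'
#' Emulates the statistical structure the prioritization index consumes:
#' a species registry with genus structure and FAO categories, regions of
#' diversity, vulnerability records, agricultural statistics, food
#' composition, government-list membership, and traditional-consumption
#' counts. Every variable's raw value is sampled so that, under the fixed
#' normalization bounds written into the returned config, it normalizes into
#' the plateau of its planted label's membership function (`hard_mode`
#' samples from the full support instead, exercising ramps and
#' tie-breaking). Default missingness rates follow the study conditions the
#' index was built for: 62% of bank species lack economic data and 73% lack
#' food-security data.
#'
#' @param n_species Total species count (default 345: 275 bank + 70
#'   external).
#' @param fraction_ncb Fraction of species in the NCB (never-conserved)
#'   group.
#' @param missingness Named vector of per-pillar missingness rates applied to
#'   BGVCOL species: `economic`, `food_security`, `geographic`.
#' @param ensure_donors Guarantee every blanked BGVCOL species a complete
#'   congener (blanking is restricted to multi-species genera and at least
#'   one member per genus stays complete).
#' @param hard_mode Sample from trapezoid supports instead of plateaus.
#' @param seed Integer seed; the generator is deterministic given the spec.
#' @return List with `dataset` (input tables, as [load_inputs()] returns),
#'   `truth` (planted per-variable and per-pillar labels, final class, and
#'   which pillars were blanked), and `config` (run configuration with the
#'   generator's fixed normalization bounds).
#' @export
generate_synthetic <- function(n_species = 345,
                               fraction_ncb = 70 / 345,
                               missingness = c(economic = 0.62,
                                               food_security = 0.73,
                                               geographic = 0),
                               ensure_donors = TRUE,
                               hard_mode = FALSE,
                               seed = 1L) {
  stopifnot(n_species >= 4, fraction_ncb >= 0, fraction_ncb <= 1,
            all(missingness >= 0 & missingness <= 1))
  set.seed(seed)
  cfg <- default_config()
  # fixed normalization bounds so plateau sampling inverts exactly
  inc_hi <- log10(50000)               # income spans 1..50,000 USD/ha (log10)
  laf_hi <- 5.28                       # observed Lafay range upper bound
  yld_hi <- 20                         # t/ha upper bound, all FAO groups
  cfg$normalization$income$lo <- 0
  cfg$normalization$income$hi <- inc_hi
  cfg$normalization$lafay$lo <- 0
  cfg$normalization$lafay$hi <- laf_hi
  cfg$normalization$yield$bounds <- setNames(
    lapply(fao_categories(), function(g) c(0, yld_hi)), fao_categories())
  cfg$normalization$nutrition$bounds <- list(
    ca = c(0, 100), fe = c(0, 100), zn = c(0, 100), energy = c(0, 100))
  mn <- cfg$targets
  cfg$normalization$affordability$bounds <- list(
    ca = c(0, 100 / mn$ca), fe = c(0, 100 / mn$fe),
    zn = c(0, 100 / mn$zn), energy = c(0, 100 / mn$energy))

  n_ncb <- round(n_species * fraction_ncb)
  n_bg <- n_species - n_ncb
  # genus structure: mostly multi-species genera so gene-pool donors exist
  genus_pool <- character(0)
  gi <- 0
  while (length(genus_pool) < n_species) {
    gi <- gi + 1
    # a few large genera dominate real collections; sizes skew accordingly
    size <- sample(c(1, 2, 3, 4, 6, 8, 12, 20), 1,
                   prob = c(0.08, 0.14, 0.2, 0.2, 0.15, 0.12, 0.07, 0.04))
    genus_pool <- c(genus_pool, rep(sprintf("Genus%03d", gi), size))
  }
  genus <- genus_pool[seq_len(n_species)]
  ids <- sprintf("SP%04d", seq_len(n_species))
  species <- data.frame(
    species_id = ids,
    taxon = paste(genus, sprintf("species%04d", seq_len(n_species))),
    group = c(rep("BGVCOL", n_bg), rep("NCB", n_ncb)),
    genus = genus,
    # FAO category follows genus so PCG fallbacks are coherent
    fao_category = setNames(sample(fao_categories(), length(unique(genus)),
                                   replace = TRUE),
                            unique(genus))[genus],
    stringsAsFactors = FALSE)

  voc <- region_vocabulary()
  geo_lab <- sample(c("local", "close", "distant"), n_species, replace = TRUE,
                    prob = c(0.44, 0.19, 0.37))
  regions <- do.call(rbind, lapply(seq_len(n_species), function(i) {
    r <- switch(geo_lab[i],
      local = c(sample(voc$local, 1),
                if (stats::runif(1) < 0.3) sample(voc$distant, 1)),
      close = c(sample(voc$close, 1),
                if (stats::runif(1) < 0.3) sample(voc$distant, 1)),
      distant = sample(voc$distant, sample(1:2, 1)))
    data.frame(species_id = ids[i], region = r, stringsAsFactors = FALSE)
  }))

  vul_lab <- sample(c("threatened", "minor_concern", "not_evaluated"),
                    n_species, replace = TRUE, prob = c(0.08, 0.45, 0.47))
  vulnerability <- data.frame(
    species_id = ids,
    national_category = vapply(vul_lab, function(l) switch(l,
      threatened = sample(c("endangered", "vulnerable"), 1),
      minor_concern = sample(c("near threatened", "minor concern"), 1),
      not_evaluated = NA_character_), character(1)),
    international_category = NA_character_,
    stringsAsFactors = FALSE)

  three <- c("low", "medium", "high")
  lab <- data.frame(
    species_id = ids,
    lafay = sample(three, n_species, TRUE),
    yield = sample(three, n_species, TRUE),
    income = sample(three, n_species, TRUE),
    coverage = c(undetermined = "undetermined", low = "narrow",
                 medium = "medium", high = "large")[
                   sample(three, n_species, TRUE)],
    gov_list = sample(c("included", "not_included"), n_species, TRUE),
    traditional = sample(c("narrow", "medium", "large"), n_species, TRUE),
    nutrition = sample(three, n_species, TRUE),
    affordability = sample(three, n_species, TRUE),
    stringsAsFactors = FALSE)

  ms <- cfg$membership
  tm <- cfg$total_municipalities
  economics <- do.call(rbind, lapply(seq_len(n_species), function(i) {
    u_inc <- .plateau_sample(ms$income, lab$income[i], hard = hard_mode)
    u_laf <- .plateau_sample(ms$lafay, lab$lafay[i], hard = hard_mode)
    u_yld <- .plateau_sample(ms$yield, lab$yield[i], hard = hard_mode)
    u_cov <- .plateau_sample(ms$coverage, lab$coverage[i], hard = hard_mode)
    inc <- 10^((u_inc - 1) / 99 * inc_hi)
    laf <- (u_laf - 1) / 99 * laf_hi
    yld <- (u_yld - 1) / 99 * yld_hi
    area <- stats::runif(1, 5, 500)
    production <- yld * area
    price <- inc * area / production
    if (laf >= 1) { exports <- production * (1 - 1 / laf); imports <- 0 }
    else { imports <- production * (1 / laf - 1); exports <- 0 }
    data.frame(species_id = ids[i], year = 2017L,
               production_t = production, area_ha = area,
               price_usd_t = price, imports_t = imports,
               exports_t = exports,
               municipalities = round(u_cov * tm / 100),
               stringsAsFactors = FALSE)
  }))

  cd <- 100  # g/day consumption used throughout the fixture
  nutrition <- do.call(rbind, lapply(seq_len(n_species), function(i) {
    u_n <- .plateau_sample(ms$nutrition, lab$nutrition[i], hard = hard_mode)
    u_a <- .plateau_sample(ms$affordability, lab$affordability[i],
                           hard = hard_mode)
    cij <- (u_n - 1) * 100 / 99        # percent of daily target, all j
    price <- (u_a - 1) * cij / 99      # USD per 100 g
    data.frame(species_id = ids[i],
               ca_mg_100g = cij * mn$ca / cd,
               fe_mg_100g = cij * mn$fe / cd,
               zn_mg_100g = cij * mn$zn / cd,
               energy_kcal_100g = cij * mn$energy / cd,
               consumption_g_day = cd,
               price_usd_100g = price,
               stringsAsFactors = FALSE)
  }))

  government_list <- data.frame(species_id = ids,
                                included = lab$gov_list == "included",
                                stringsAsFactors = FALSE)
  traditional <- data.frame(
    species_id = ids,
    n_regions = vapply(lab$traditional, function(l) switch(l,
      narrow = sample(1:3, 1), medium = sample(4:6, 1),
      large = sample(7:11, 1)), numeric(1)),
    stringsAsFactors = FALSE)

  # ground-truth pillar labels and final class from the planted labels
  eco <- lapply(seq_len(n_species), function(i)
    classify_economic(unlist(lab[i, c("lafay", "yield", "income",
                                      "coverage")]), cfg))
  fs <- lapply(seq_len(n_species), function(i)
    classify_food_security(unlist(lab[i, c("gov_list", "traditional",
                                           "nutrition", "affordability")]),
                           cfg))
  truth <- cbind(lab, data.frame(
    geographic = geo_lab, vulnerability = vul_lab,
    economic = vapply(eco, `[[`, character(1), "label"),
    food_security = vapply(fs, `[[`, character(1), "label"),
    stringsAsFactors = FALSE))
  truth$final_class <- vapply(seq_len(n_species), function(i) final_class(
    ordinal_level(truth$geographic[i], "geographic"),
    ordinal_level(truth$vulnerability[i], "vulnerability"),
    ordinal_level(truth$economic[i], "economic"),
    ordinal_level(truth$food_security[i], "food_security")), character(1))

  # per-pillar missingness on BGVCOL species
  blank <- function(rate) {
    target <- round(rate * n_bg)
    if (target == 0) return(character(0))
    eligible <- seq_len(n_bg)
    if (ensure_donors) {
      # keep one complete member per genus; skip singleton genera
      keep <- unlist(lapply(split(seq_len(n_bg), genus[seq_len(n_bg)]),
                            function(idx)
                              if (length(idx) == 1L) idx else idx[1]))
      eligible <- setdiff(eligible, keep)
    }
    ids[eligible[sample.int(length(eligible),
                            min(target, length(eligible)))]]
  }
  miss <- function(nm) if (nm %in% names(missingness)) missingness[[nm]] else 0
  blank_econ <- blank(miss("economic"))
  blank_food <- blank(miss("food_security"))
  blank_geo <- blank(miss("geographic"))
  economics <- economics[!economics$species_id %in% blank_econ, ]
  nutrition <- nutrition[!nutrition$species_id %in% blank_food, ]
  government_list <- government_list[
    !government_list$species_id %in% blank_food, ]
  traditional <- traditional[!traditional$species_id %in% blank_food, ]
  regions <- regions[!regions$species_id %in% blank_geo, ]
  truth$blank_economic <- truth$species_id %in% blank_econ
  truth$blank_food_security <- truth$species_id %in% blank_food
  truth$blank_geographic <- truth$species_id %in% blank_geo

  ds <- structure(list(species = species, regions = regions,
                       vulnerability = vulnerability, economics = economics,
                       nutrition = nutrition,
                       government_list = government_list,
                       traditional = traditional),
                  class = c("agroprior_dataset", "list"))
  list(dataset = ds, truth = truth, config = cfg)
}

#' Write a dataset's tables to CSV files
#'
#' @param ds An `agroprior_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(.schemas))
    utils::write.csv(ds[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(dir)
}
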