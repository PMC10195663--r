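# Schema-validated readers, the normalization/fuzzification step, and the
# end-to-end pipeline. CSV dialect: comma-separated, UTF-8, header row,
# decimal point ".". Missing cells stay missing (NA) all the way down and
# surface as "undetermined" labels.

.schemas <- list(
  species = c("species_id", "taxon", "group", "genus", "fao_category"),
  regions = c("species_id", "region"),
  vulnerability = c("species_id", "national_category",
                    "international_category"),
  economics = c("species_id", "year", "production_t", "area_ha",
                "price_usd_t", "imports_t", "exports_t", "municipalities"),
  nutrition = c("species_id", "ca_mg_100g", "fe_mg_100g", "zn_mg_100g",
                "energy_kcal_100g", "consumption_g_day", "price_usd_100g"),
  government_list = c("species_id", "included"),
  traditional = c("species_id", "n_regions")
)

.read_table <- function(dir, name, required = FALSE) {
  path <- file.path(dir, paste0(name, ".csv"))
  if (!file.exists(path)) {
    if (required) stop("required input file missing: ", path)
    df <- as.data.frame(setNames(
      rep(list(character(0)), length(.schemas[[name]])), .schemas[[name]]))
    return(df)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  miss <- setdiff(.schemas[[name]], names(df))
  if (length(miss))
    stop(name, ".csv missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' Load and validate the input tables
#'
#' Reads the seven input CSVs from a directory (`species.csv` is required;
#' the others may be absent or empty, in which case their variables are
#' fully missing). Validates species-id uniqueness, group codes
#' (BGVCOL/NCB), the FAO category, region, and vulnerability vocabularies,
#' and that every sub-table row refers to a registered species; errors name
#' the offending file and row.
#'
#' @param dir Directory containing the CSV files.
#' @return A named list of data frames (class `agroprior_dataset`).
#' @export
load_inputs <- function(dir) {
  ds <- lapply(setNames(nm = names(.schemas)), function(nm)
    .read_table(dir, nm, required = nm == "species"))
  sp <- ds$species
  if (nrow(sp) == 0L) stop("species.csv has no rows")
  if (anyDuplicated(sp$species_id))
    stop("duplicate species_id in species.csv: ",
         paste(unique(sp$species_id[duplicated(sp$species_id)]),
               collapse = ", "))
  bad <- which(!sp$group %in% c("BGVCOL", "NCB"))
  if (length(bad))
    stop("species.csv row ", bad[1], ": group must be BGVCOL or NCB, got '",
         sp$group[bad[1]], "'")
  bad <- which(!is.na(sp$fao_category) &
                 !sp$fao_category %in% fao_categories())
  if (length(bad))
    stop("species.csv row ", bad[1], ": unknown FAO category '",
         sp$fao_category[bad[1]], "'; valid: ",
         paste(fao_categories(), collapse = ", "))
  voc <- unlist(region_vocabulary())
  bad <- which(!is.na(ds$regions$region) & !ds$regions$region %in% voc)
  if (length(bad))
    stop("regions.csv row ", bad[1], ": unknown region '",
         ds$regions$region[bad[1]], "'; the valid regions are: ",
         paste(voc, collapse = ", "))
  vv <- vulnerability_vocabulary()
  for (col in c("national_category", "international_category")) {
    which_voc <- if (col == "national_category") vv$national else
      c(vv$international, "least concern")
    bad <- which(!is.na(ds$vulnerability[[col]]) &
                   !tolower(ds$vulnerability[[col]]) %in% which_voc)
    if (length(bad))
      stop("vulnerability.csv row ", bad[1], ": unknown ", col, " '",
           ds$vulnerability[[col]][bad[1]], "'")
  }
  for (nm in setdiff(names(ds), "species")) {
    bad <- which(!ds[[nm]]$species_id %in% sp$species_id)
    if (length(bad))
      stop(nm, ".csv row ", bad[1], ": species_id '",
           ds[[nm]]$species_id[bad[1]], "' not in species.csv")
  }
  structure(ds, class = c("agroprior_dataset", "list"))
}

.latest_complete <- function(df) {
  ok <- stats::complete.cases(df[, c("price_usd_t", "production_t",
                                     "area_ha")])
  if (!any(ok)) return(NULL)
  df[ok, ][which.max(df$year[ok]), ]
}

#' Compute the per-species indicator table
#'
#' Raw economic and nutritional indicators for every registered species:
#' income per hectare (latest year with complete price, production, and
#' area), Lafay index (flows averaged over the available years), municipality
#' coverage (latest year), yield (multi-year means), micronutrient
#' contributions `C_ij` and nutrient-price ratios for calcium, iron, zinc,
#' and energy, traditional-consumption region counts, and government-list
#' membership. Every column gets a companion `<name>_missing` flag.
#'
#' @param ds Dataset from [load_inputs()] or [generate_synthetic()].
#' @param cfg Run configuration.
#' @return `data.frame`, one row per species.
#' @export
indicator_table <- function(ds, cfg = default_config()) {
  sp <- ds$species
  tm <- cfg$total_municipalities
  one <- function(id) {
    ec <- ds$economics[ds$economics$species_id == id, , drop = FALSE]
    nu <- ds$nutrition[ds$nutrition$species_id == id, , drop = FALSE]
    tr <- ds$traditional[ds$traditional$species_id == id, , drop = FALSE]
    gv <- ds$government_list[ds$government_list$species_id == id, ,
                             drop = FALSE]
    last <- .latest_complete(ec)
    inc <- if (is.null(last)) NA_real_ else
      income(last$price_usd_t, last$production_t, last$area_ha)
    yld <- if (nrow(ec)) crop_yield(ec$production_t, ec$area_ha) else
      NA_real_
    laf <- if (nrow(ec) && any(!is.na(ec$production_t)) &&
               any(!is.na(ec$imports_t)) && any(!is.na(ec$exports_t))) {
      lafay(mean(ec$production_t, na.rm = TRUE),
            mean(ec$imports_t, na.rm = TRUE),
            mean(ec$exports_t, na.rm = TRUE))
    } else NA_real_
    mun <- ec$municipalities[!is.na(ec$municipalities)]
    cov <- if (length(mun))
      municipality_coverage(mun[length(mun)], tm) else NA_real_
    cc <- function(col, target) {
      if (!nrow(nu)) return(NA_real_)
      nutritional_contribution(nu$consumption_g_day[1], nu[[col]][1], target)
    }
    rr <- function(col) {
      if (!nrow(nu)) return(NA_real_)
      nutrient_price_ratio(nu$price_usd_100g[1], nu[[col]][1])
    }
    tg <- cfg$targets
    data.frame(
      species_id = id,
      income = inc, lafay = laf, yield = yld, coverage = cov,
      c_ca = cc("ca_mg_100g", tg$ca), c_fe = cc("fe_mg_100g", tg$fe),
      c_zn = cc("zn_mg_100g", tg$zn),
      c_energy = cc("energy_kcal_100g", tg$energy),
      r_ca = rr("ca_mg_100g"), r_fe = rr("fe_mg_100g"),
      r_zn = rr("zn_mg_100g"), r_energy = rr("energy_kcal_100g"),
      n_regions = if (nrow(tr)) tr$n_regions[1] else NA_real_,
      gov_included = if (nrow(gv)) as.logical(gv$included[1]) else NA,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(sp$species_id, one))
  for (col in setdiff(names(out), "species_id"))
    out[[paste0(col, "_missing")]] <- is.na(out[[col]])
  out
}

.norm_values <- function(x, spec, log10_first = FALSE, clip_zero = FALSE) {
  if (clip_zero) x <- pmax(x, 0)
  if (log10_first) {
    x[!is.na(x) & x <= 0] <- NA_real_
    x <- log10(x)
  }
  range_normalize(x, lo = spec$lo %||% spec$bounds[1] %||% NULL,
                  hi = spec$hi %||% spec$bounds[2] %||% NULL)
}

.label_one <- function(x, sets) {
  if (is.na(x)) "undetermined" else fuzzify(x, sets)$label
}

#' Fuzzify indicators into per-variable labels
#'
#' Applies the normalization the index prescribes (log then range
#' normalization for income; zero-clipping then range normalization for the
#' Lafay index; range normalization within each FAO food category for yield;
#' per-micronutrient range normalization for contributions and price
#' ratios), fuzzifies each normalized value against its membership sets, and
#' derives the traditional-consumption and government-list labels. The
#' nutrition and affordability micronutrient labels are summarized into one
#' label each via their own decision-index rule base.
#'
#' @param ind Indicator table from [indicator_table()].
#' @param ds The dataset (for regions, vulnerability, FAO categories).
#' @param cfg Run configuration.
#' @return Label table consumed by [classify_pillars()] /
#'   [apply_imputation()]; micronutrient-level labels are kept as
#'   `nutr_*` / `aff_*` columns for audit.
#' @export
label_table <- function(ind, ds, cfg = default_config()) {
  mb <- lapply(cfg$membership, build_sets)
  nz <- cfg$normalization
  sp <- ds$species
  inc_n <- .norm_values(ind$income, nz$income, log10_first = TRUE)
  laf_n <- .norm_values(ind$lafay, nz$lafay,
                        clip_zero = isTRUE(nz$lafay$clip_zero))
  yld_n <- rep(NA_real_, nrow(ind))
  fao <- sp$fao_category[match(ind$species_id, sp$species_id)]
  for (g in unique(fao[!is.na(fao)])) {
    sel <- !is.na(fao) & fao == g
    spec <- list(bounds = nz$yield$bounds[[g]])
    yld_n[sel] <- .norm_values(ind$yield[sel], spec)
  }
  lab <- data.frame(species_id = ind$species_id, stringsAsFactors = FALSE)
  lab$income <- vapply(inc_n, .label_one, character(1), sets = mb$income)
  lab$lafay <- vapply(laf_n, .label_one, character(1), sets = mb$lafay)
  lab$yield <- vapply(yld_n, .label_one, character(1), sets = mb$yield)
  lab$coverage <- vapply(ind$coverage, .label_one, character(1),
                         sets = mb$coverage)
  for (j in c("ca", "fe", "zn", "energy")) {
    cn <- .norm_values(ind[[paste0("c_", j)]],
                       list(bounds = nz$nutrition$bounds[[j]]))
    rn <- .norm_values(ind[[paste0("r_", j)]],
                       list(bounds = nz$affordability$bounds[[j]]))
    lab[[paste0("nutr_", j)]] <- vapply(cn, .label_one, character(1),
                                        sets = mb$nutrition)
    lab[[paste0("aff_", j)]] <- vapply(rn, .label_one, character(1),
                                       sets = mb$affordability)
  }
  lab$nutrition <- vapply(seq_len(nrow(lab)), function(i)
    classify_micronutrient_block(
      c(ca = lab$nutr_ca[i], fe = lab$nutr_fe[i], zn = lab$nutr_zn[i],
        energy = lab$nutr_energy[i]), "nutrition", cfg), character(1))
  lab$affordability <- vapply(seq_len(nrow(lab)), function(i)
    classify_micronutrient_block(
      c(ca = lab$aff_ca[i], fe = lab$aff_fe[i], zn = lab$aff_zn[i],
        energy = lab$aff_energy[i]), "affordability", cfg), character(1))
  br <- cfg$traditional_breaks
  lab$traditional <- vapply(ind$n_regions, function(n) {
    if (is.na(n)) "undetermined"
    else if (n >= br$large[1]) "large"
    else if (n >= br$medium[1]) "medium"
    else "narrow"
  }, character(1))
  lab$gov_list <- ifelse(is.na(ind$gov_included), "undetermined",
                         ifelse(ind$gov_included, "included", "not_included"))
  lab$geographic <- vapply(ind$species_id, function(id)
    classify_geographic(ds$regions$region[ds$regions$species_id == id]),
    character(1))
  lab$vulnerability <- vapply(ind$species_id, function(id) {
    vr <- ds$vulnerability[ds$vulnerability$species_id == id, , drop = FALSE]
    if (!nrow(vr)) return("not_evaluated")
    classify_vulnerability(vr$national_category[1],
                           vr$international_category[1])
  }, character(1))
  rownames(lab) <- NULL
  lab
}

#' Run the full prioritization pipeline
#'
#' Indicators -> normalization and fuzzification -> pillar classification ->
#' donor imputation with uncertainty tags -> final ranking. Deterministic
#' given its inputs. When `output_dir` is given, writes `indicators.csv`,
#' `labels.csv`, `pillars.csv`, `imputation_audit.csv`, `ranked.csv`, and
#' `summary.json` (per-class and per-tag counts).
#'
#' @param ds Dataset from [load_inputs()] or [generate_synthetic()].
#' @param cfg Run configuration (validated before use).
#' @param output_dir Optional output directory (created if needed).
#' @return List with `indicators`, `labels`, `pillars`, `audit`, `ranked`,
#'   `summary`.
#' @export
run_pipeline <- function(ds, cfg = default_config(), output_dir = NULL) {
  validate_config(cfg)
  ind <- indicator_table(ds, cfg)
  lab <- label_table(ind, ds, cfg)
  # raw-data missingness flags drive imputation eligibility
  miss <- data.frame(
    species_id = ind$species_id,
    lafay = ind$lafay_missing, yield = ind$yield_missing,
    income = ind$income_missing, coverage = ind$coverage_missing,
    gov_list = ind$gov_included_missing,
    traditional = ind$n_regions_missing,
    nutrition = ind$c_ca_missing & ind$c_fe_missing & ind$c_zn_missing &
      ind$c_energy_missing,
    affordability = ind$r_ca_missing & ind$r_fe_missing &
      ind$r_zn_missing & ind$r_energy_missing,
    geographic = !ind$species_id %in% ds$regions$species_id,
    stringsAsFactors = FALSE)
  imp <- apply_imputation(lab, ds$species, cfg, missing = miss)
  pil <- imp$pillars
  pil$group <- ds$species$group[match(pil$species_id,
                                      ds$species$species_id)]
  ranked <- rank_all(pil, cfg)
  summary <- list(
    n_species = nrow(ranked),
    class_counts = lapply(split(ranked, ranked$group), function(d)
      as.list(table(factor(d$final_class,
                           levels = c("high", "medium", "low"))))),
    pillar_counts = lapply(
      c(geographic = "geographic", vulnerability = "vulnerability",
        economic = "economic", food_security = "food_security"),
      function(p) as.list(table(ranked[[p]]))),
    uncertainty_counts = as.list(table(ranked$uncertainty))
  )
  out <- list(indicators = ind, labels = imp$labels, pillars = pil,
              audit = imp$audit, ranked = ranked, summary = summary)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, nm) utils::write.csv(
      df, file.path(output_dir, nm), row.names = FALSE, fileEncoding = "UTF-8")
    wr(ind, "indicators.csv")
    wr(imp$labels, "labels.csv")
    wr(pil, "pillars.csv")
    wr(imp$audit, "imputation_audit.csv")
    wr(ranked, "ranked.csv")
    jsonlite::write_json(summary, file.path(output_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}
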