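# Run configuration: every membership parameter, weight, threshold and
# vocabulary lives here, none in code paths. The defaults are the published
# parameterization of the index; load_config()/write_config() round-trip the
# whole structure through YAML so a run is fully described by one file.

#' Controlled vocabulary of the 26 world regions of crop diversity
#'
#' Regions are grouped into three origin classes relative to Colombia:
#' `local` (contains Colombia), `close` (neighboring), `distant` (the rest).
#' The shipped list carries the region names as published (duplicates
#' removed).
#'
#' @return Named list with `local`, `close`, `distant` character vectors.
#' @export
region_vocabulary <- function() {
  list(
    local = c("Andes", "Tropical South America"),
    close = c("Caribbean", "Central America and Mexico",
              "Temperate South America"),
    distant = c("Australia", "Indian Ocean Islands", "Central Africa",
                "East Africa", "Southern Africa", "West Africa",
                "North America", "Asia", "West Asia", "South Asia",
                "Southeast Asia", "Central Asia", "East Asia", "Europe",
                "Southeast Europe", "South Mediterranean",
                "Northeast Europe", "Southwest Europe", "Northwest Europe",
                "East Mediterranean")
  )
}

#' FAO food categories used to stratify yields and imputation donors
#' @return Character vector of the nine category names.
#' @export
fao_categories <- function() {
  c("cereals", "vegetables and melons", "fruits and nuts", "oilseed crops",
    "root and tuber crops", "beverage and spice crops", "leguminous crops",
    "sugar crops", "other crops")
}

#' Vulnerability source vocabularies
#'
#' The national catalog uses five categories and the international databases
#' six; both are merged downstream into threatened / minor concern / not
#' evaluated.
#'
#' @return Named list with `national` and `international` character vectors.
#' @export
vulnerability_vocabulary <- function() {
  list(
    national = c("endangered", "vulnerable", "near threatened",
                 "minor concern", "not evaluated"),
    international = c("critically endangered", "endangered", "vulnerable",
                      "near threatened", "minor concern", "not evaluated")
  )
}

.mf_spec <- function(label, priority, shape, ...) {
  c(list(label = label, priority = priority, shape = shape), list(...))
}

#' Default run configuration
#'
#' Returns the full parameterization of the prioritization index: the
#' `[0, 100]` universe, the published singleton/trapezoid/Gaussian
#' membership parameters for every variable and output, decision-index
#' scores, weights (0.25 each) and class thresholds for the two
#' rule-aggregated pillars, normalization settings, the total municipality
#' count, and empty per-species overrides.
#'
#' @param total_municipalities Total number of municipalities in the country
#'   (denominator of municipality coverage).
#' @return A nested list of class `agroprior_config`.
#' @export
default_config <- function(total_municipalities = 1122) {
  cfg <- list(
    universe = list(lower = 0, upper = 100, resolution = 0.01),
    total_municipalities = total_municipalities,
    weights = list(economic = c(lafay = 0.25, yield = 0.25, income = 0.25,
                                coverage = 0.25),
                   food_security = c(gov_list = 0.25, traditional = 0.25,
                                     nutrition = 0.25, affordability = 0.25)),
    # half-open class intervals on the decision index:
    # [0, und) undetermined, [und, low_hi) low, [low_hi, med_hi) medium,
    # [med_hi, 1] high
    thresholds = list(
      economic = c(und = 0.25, low_hi = 0.46, med_hi = 0.65),
      food_security = c(und = 0.25, low_hi = 0.45, med_hi = 0.65)
    ),
    scores = list(
      economic = c(undetermined = 0, low = 1, medium = 2, high = 3),
      gov_list = c(undetermined = 0, not_included = 0, included = 3),
      traditional = c(undetermined = 0, narrow = 0, medium = 1, large = 3),
      nutrition = c(undetermined = 0, low = 1, medium = 2, high = 3),
      affordability = c(undetermined = 0, low = 1, medium = 2, high = 3)
    ),
    invert_affordability = FALSE,
    # micronutrient daily targets for the focal population (mg/day; kcal/day
    # for energy) -- configuration values, replace with the national dietary
    # reference for a real run
    targets = list(ca = 1000, fe = 11, zn = 5, energy = 1350),
    normalization = list(
      income = list(method = "log_range", lo = NULL, hi = NULL),
      lafay = list(method = "range", lo = NULL, hi = NULL, clip_zero = TRUE),
      yield = list(method = "range", by_fao_group = TRUE, bounds = NULL),
      nutrition = list(method = "range", bounds = NULL),
      affordability = list(method = "range", bounds = NULL)
    ),
    traditional_breaks = list(narrow = c(1, 3), medium = c(4, 6),
                              large = c(7, 11)),
    membership = list(
      geographic = list(
        .mf_spec("distant", "low", "singleton", a = 0),
        .mf_spec("close", "middle", "singleton", a = 45),
        .mf_spec("local", "high", "singleton", a = 70)
      ),
      vulnerability = list(
        .mf_spec("not_evaluated", "undetermined", "singleton", a = 0),
        .mf_spec("minor_concern", "low", "singleton", a = 30),
        .mf_spec("threatened", "high", "singleton", a = 70)
      ),
      lafay = list(
        .mf_spec("undetermined", "undetermined", "singleton", a = 0),
        .mf_spec("low", "low", "trapezoid", a = 1, m = 5.2, n = 10.4,
                 b = 17.68),
        .mf_spec("medium", "middle", "trapezoid", a = 10.4, m = 20.8,
                 n = 20.8, b = 31.12),
        .mf_spec("high", "high", "trapezoid", a = 20.8, m = 31.2, n = 100,
                 b = 100)
      ),
      yield = list(
        .mf_spec("undetermined", "undetermined", "singleton", a = 0),
        .mf_spec("low", "low", "trapezoid", a = 4.9, m = 5, n = 28.2,
                 b = 37.6),
        .mf_spec("medium", "middle", "trapezoid", a = 28.2, m = 37.6, n = 54,
                 b = 65.2),
        .mf_spec("high", "high", "trapezoid", a = 54, m = 65.2, n = 100,
                 b = 100)
      ),
      income = list(
        .mf_spec("undetermined", "undetermined", "singleton", a = 0),
        .mf_spec("low", "low", "trapezoid", a = 4.9, m = 5, n = 28.2,
                 b = 37.6),
        .mf_spec("medium", "middle", "trapezoid", a = 28.2, m = 37.6, n = 54,
                 b = 65.2),
        .mf_spec("high", "high", "trapezoid", a = 54, m = 65.2, n = 105,
                 b = 110)
      ),
      coverage = list(
        .mf_spec("undetermined", "undetermined", "singleton", a = 0),
        .mf_spec("narrow", "low", "trapezoid", a = 0.99, m = 1, n = 15,
                 b = 30),
        .mf_spec("medium", "middle", "trapezoid", a = 20, m = 25, n = 50,
                 b = 60),
        .mf_spec("large", "high", "trapezoid", a = 55, m = 60, n = 101,
                 b = 105)
      ),
      economic_output = list(
        .mf_spec("undetermined", "undetermined", "trapezoid", a = 0,
                 m = 0.01, n = 9.9, b = 10),
        .mf_spec("low", "low", "trapezoid", a = 10, m = 25, n = 30, b = 45),
        .mf_spec("medium", "middle", "trapezoid", a = 30, m = 45, n = 50,
                 b = 65),
        .mf_spec("high", "high", "trapezoid", a = 50, m = 65, n = 70, b = 85)
      ),
      gov_list = list(
        .mf_spec("not_included", "low", "singleton", a = 20),
        .mf_spec("included", "high", "singleton", a = 60)
      ),
      traditional = list(
        .mf_spec("undetermined", "undetermined", "singleton", a = 0),
        .mf_spec("narrow", "low", "trapezoid", a = 0.11, m = 1, n = 1.1,
                 b = 1.25),
        .mf_spec("medium", "middle", "trapezoid", a = 1.05, m = 1.1,
                 n = 1.15, b = 1.35),
        .mf_spec("large", "high", "trapezoid", a = 1.35, m = 19, n = 100,
                 b = 100)
      ),
      nutrition = list(
        .mf_spec("undetermined", "undetermined", "trapezoid", a = 0,
                 m = 0.01, n = 9.99, b = 10),
        .mf_spec("low", "low", "trapezoid", a = 10, m = 26, n = 30, b = 45),
        .mf_spec("medium", "middle", "trapezoid", a = 30, m = 45, n = 50,
                 b = 65),
        .mf_spec("high", "high", "trapezoid", a = 50, m = 65, n = 100,
                 b = 100)
      ),
      affordability = list(
        .mf_spec("undetermined", "undetermined", "trapezoid", a = 0,
                 m = 0.01, n = 9.99, b = 10),
        .mf_spec("low", "high", "trapezoid", a = 10, m = 26, n = 30, b = 45),
        .mf_spec("medium", "middle", "trapezoid", a = 30, m = 45, n = 50,
                 b = 65),
        .mf_spec("high", "low", "trapezoid", a = 50, m = 65, n = 100,
                 b = 100)
      ),
      food_output = list(
        .mf_spec("undetermined", "undetermined", "trapezoid", a = 0,
                 m = 0.01, n = 9.99, b = 10),
        .mf_spec("low", "low", "trapezoid", a = 10, m = 25, n = 30, b = 45),
        .mf_spec("medium", "middle", "trapezoid", a = 30, m = 45, n = 50,
                 b = 65),
        .mf_spec("high", "high", "trapezoid", a = 50, m = 65, n = 70, b = 85)
      ),
      priority_index = list(
        .mf_spec("low", "low", "gaussian", mu = 15, sigma = 5),
        .mf_spec("medium", "middle", "gaussian", mu = 55, sigma = 5),
        .mf_spec("high", "high", "gaussian", mu = 90, sigma = 5)
      )
    ),
    # per-species label overrides, e.g. list(geographic = c("Solanum x" =
    # "close")) for taxa whose origin is asserted rather than derived
    overrides = list(geographic = character(0)),
    # optional crop-group mapping (species_id -> group); gene-pool donors
    # default to shared genus when a species has no explicit group
    crop_groups = character(0)
  )
  class(cfg) <- c("agroprior_config", "list")
  validate_config(cfg)
  cfg
}

#' Build labeled fuzzy sets from a config membership block
#'
#' @param specs One element of `config$membership` (a list of parameter
#'   blocks with `label`, `priority`, `shape` and shape parameters).
#' @return List of `labeled_fuzzy_set`s, named by label.
#' @export
build_sets <- function(specs) {
  sets <- lapply(specs, function(s) {
    f <- switch(s$shape,
      singleton = mf_singleton(s$a, tol = if (is.null(s$tol)) 0.001 else s$tol),
      trapezoid = mf_trapezoid(s$a, s$m, s$n, s$b),
      gaussian  = mf_gaussian(s$mu, s$sigma),
      stop("unknown shape in membership spec: ", s$shape))
    fuzzy_set(s$label, f, priority = s$priority)
  })
  names(sets) <- vapply(specs, `[[`, character(1), "label")
  sets
}

#' Validate a run configuration
#'
#' Checks universe sanity, weight sums, threshold ordering, presence of every
#' membership block, and the validity of each membership parameter set.
#'
#' @param cfg A config list as produced by [default_config()] or
#'   [load_config()].
#' @return The config, invisibly; errors describe the first violation.
#' @export
validate_config <- function(cfg) {
  required <- c("universe", "total_municipalities", "weights", "thresholds",
                "scores", "targets", "normalization", "membership")
  missing <- setdiff(required, names(cfg))
  if (length(missing))
    stop("config missing blocks: ", paste(missing, collapse = ", "))
  do.call(universe_spec, cfg$universe)
  for (p in names(cfg$weights)) {
    w <- unlist(cfg$weights[[p]])
    if (abs(sum(w) - 1) > 1e-8)
      stop("weights for pillar '", p, "' must sum to 1 (got ", sum(w), ")")
    if (any(w < 0)) stop("weights must be non-negative")
  }
  for (p in names(cfg$thresholds)) {
    th <- unlist(cfg$thresholds[[p]])
    if (!all(names(th) == c("und", "low_hi", "med_hi")) ||
        !all(diff(c(0, th, 1)) > 0))
      stop("thresholds for '", p, "' must be increasing within (0, 1)")
  }
  blocks <- c("geographic", "vulnerability", "lafay", "yield", "income",
              "coverage", "economic_output", "gov_list", "traditional",
              "nutrition", "affordability", "food_output", "priority_index")
  miss <- setdiff(blocks, names(cfg$membership))
  if (length(miss))
    stop("config missing membership blocks: ", paste(miss, collapse = ", "))
  for (b in blocks) build_sets(cfg$membership[[b]])  # constructor validates
  if (cfg$total_municipalities <= 0)
    stop("total_municipalities must be positive")
  invisible(cfg)
}

#' Read / write a run configuration as YAML
#'
#' @param path File path.
#' @param cfg Config list to write.
#' @return `load_config()` returns a validated `agroprior_config`.
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  # yaml drops names on scalars read back as lists; re-unlist numeric maps
  for (p in names(cfg$weights)) cfg$weights[[p]] <- unlist(cfg$weights[[p]])
  for (p in names(cfg$thresholds))
    cfg$thresholds[[p]] <- unlist(cfg$thresholds[[p]])
  for (p in names(cfg$scores)) cfg$scores[[p]] <- unlist(cfg$scores[[p]])
  for (p in names(cfg$traditional_breaks))
    cfg$traditional_breaks[[p]] <- unlist(cfg$traditional_breaks[[p]])
  for (v in names(cfg$normalization)) {
    b <- cfg$normalization[[v]]$bounds
    if (!is.null(b))
      cfg$normalization[[v]]$bounds <-
        if (is.list(b) && !is.null(names(b))) lapply(b, unlist) else unlist(b)
  }
  cfg$overrides$geographic <- unlist(cfg$overrides$geographic) %||% character(0)
  cfg$crop_groups <- unlist(cfg$crop_groups) %||% character(0)
  class(cfg) <- c("agroprior_config", "list")
  validate_config(cfg)
  cfg
}

#' @rdname load_config
#' @export
write_config <- function(cfg, path) {
  # yaml serializes named atomic vectors as plain sequences; convert them to
  # maps so names survive the round trip
  prep <- function(x) {
    if (is.list(x)) lapply(x, prep)
    else if (is.atomic(x) && !is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(prep(unclass(cfg)), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
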