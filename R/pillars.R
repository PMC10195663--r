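# The four pillar classifiers. Geographic origin and vulnerability are
# single-variable merges of controlled vocabularies; economic benefits and
# food security importance aggregate four labeled variables each through the
# weighted decision-index rule base.

#' Classify geographic origin from regions of diversity
#'
#' A species is `local` if any of its regions of diversity contains Colombia
#' (Andes, Tropical South America), `close` if (not local and) any region
#' neighbors those (Caribbean, Central America and Mexico, Temperate South
#' America), `distant` otherwise, and `undetermined` with no region data.
#'
#' @param regions Character vector of regions from [region_vocabulary()]
#'   (possibly empty or `NA`).
#' @return One of `"local"`, `"close"`, `"distant"`, `"undetermined"`.
#' @export
classify_geographic <- function(regions) {
  voc <- region_vocabulary()
  regions <- regions[!is.na(regions)]
  if (length(regions) == 0L) return("undetermined")
  unknown <- setdiff(regions, unlist(voc))
  if (length(unknown))
    stop("unknown region(s): ", paste(unknown, collapse = ", "),
         "; valid regions are: ", paste(unlist(voc), collapse = ", "))
  if (any(regions %in% voc$local)) return("local")
  if (any(regions %in% voc$close)) return("close")
  "distant"
}

#' Merge national and international vulnerability categories
#'
#' The national catalog (5 categories) and international databases (6) are
#' merged into three: `threatened` (endangered or vulnerable nationally;
#' critically endangered, endangered or vulnerable internationally),
#' `minor_concern` (near threatened or minor/least concern in either source,
#' none threatened), and `not_evaluated` otherwise. When sources disagree the
#' more severe one wins.
#'
#' @param national,international Category strings or `NA`.
#' @return One of `"threatened"`, `"minor_concern"`, `"not_evaluated"`.
#' @export
classify_vulnerability <- function(national = NA, international = NA) {
  norm <- function(x) {
    x <- tolower(trimws(as.character(x)))
    x[x %in% c("least concern", "least/minor concern")] <- "minor concern"
    x
  }
  voc <- vulnerability_vocabulary()
  nat <- norm(national); int <- norm(international)
  if (!is.na(national) && !nat %in% voc$national)
    stop("unknown national vulnerability category: ", national)
  if (!is.na(international) && !int %in% voc$international)
    stop("unknown international vulnerability category: ", international)
  threat_nat <- c("endangered", "vulnerable")
  threat_int <- c("critically endangered", "endangered", "vulnerable")
  minor <- c("near threatened", "minor concern")
  if ((!is.na(nat) && nat %in% threat_nat) ||
      (!is.na(int) && int %in% threat_int)) return("threatened")
  if ((!is.na(nat) && nat %in% minor) ||
      (!is.na(int) && int %in% minor)) return("minor_concern")
  "not_evaluated"
}

.class_from_id <- function(id, thresholds) {
  th <- unlist(thresholds)
  if (id < th[["und"]]) "undetermined"
  else if (id < th[["low_hi"]]) "low"
  else if (id < th[["med_hi"]]) "medium"
  else "high"
}

#' Weighted decision-index aggregation of four labeled variables
#'
#' Each variable's label carries an ordinal score `S_z` (0 undetermined, up
#' to 3 high); the decision index is `sum(S_z * w_z) / 4` with weights
#' summing to 1, so a homogeneous combination of rank-`s` labels lands at
#' `s/4`. The index is classified by half-open intervals:
#' `[0, und)` undetermined, `[und, low_hi)` low, `[low_hi, med_hi)` medium,
#' `[med_hi, 1]` high.
#'
#' @param labels Named character vector: one label per variable.
#' @param scores Named list: per-variable named score vectors (label ->
#'   score), or one shared named score vector.
#' @param weights Named numeric vector of variable weights summing to 1.
#' @param thresholds Named vector `c(und=, low_hi=, med_hi=)`.
#' @return List with `decision_index` in `[0, 1]` and `class`.
#' @export
aggregate_decision_index <- function(labels, scores, weights, thresholds) {
  stopifnot(length(labels) == length(weights),
            all(names(labels) %in% names(weights)))
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  s <- vapply(names(labels), function(v) {
    tab <- if (is.list(scores)) scores[[v]] else scores
    if (is.null(tab)) stop("no score table for variable '", v, "'")
    if (!labels[[v]] %in% names(tab))
      stop("unknown label '", labels[[v]], "' for variable '", v, "'")
    tab[[labels[[v]]]]
  }, numeric(1))
  id <- sum(s * weights[names(labels)]) / 4
  list(decision_index = id, class = .class_from_id(id, thresholds))
}

#' Classify the economic benefits pillar
#'
#' Aggregates the labels of the Lafay index, yield, income, and municipality
#' coverage (scores 0/1/2/3 for undetermined/low or narrow/medium/high or
#' large) into the pillar class via the decision index.
#'
#' @param labels Named character vector with entries `lafay`, `yield`,
#'   `income`, `coverage`.
#' @param cfg Run configuration.
#' @return List with `pillar`, `label`, `decision_index`.
#' @export
classify_economic <- function(labels, cfg = default_config()) {
  stopifnot(setequal(names(labels), c("lafay", "yield", "income", "coverage")))
  sc <- cfg$scores$economic
  coverage_sc <- c(undetermined = 0, narrow = 1, medium = 2, large = 3)
  res <- aggregate_decision_index(
    labels,
    scores = list(lafay = sc, yield = sc, income = sc, coverage = coverage_sc),
    weights = cfg$weights$economic,
    thresholds = cfg$thresholds$economic)
  list(pillar = "economic", label = res$class,
       decision_index = res$decision_index)
}

#' Classify a micronutrient sub-block (nutritional contribution or
#' affordability)
#'
#' Both food-security sub-variables are themselves four-input rule bases:
#' one label per micronutrient (calcium, iron, zinc, energy), scores
#' 0/1/2/3, equal weights, economic-style thresholds. Returns the block's
#' summary label used as one input of the food-security pillar.
#'
#' @param labels Named character vector with entries `ca`, `fe`, `zn`,
#'   `energy`.
#' @param which `"nutrition"` or `"affordability"`.
#' @param cfg Run configuration.
#' @return Summary label (`undetermined`/`low`/`medium`/`high`).
#' @export
classify_micronutrient_block <- function(labels, which = c("nutrition",
                                                           "affordability"),
                                         cfg = default_config()) {
  which <- match.arg(which)
  stopifnot(setequal(names(labels), c("ca", "fe", "zn", "energy")))
  sc <- cfg$scores[[which]]
  w <- rep(0.25, 4); names(w) <- names(labels)
  res <- aggregate_decision_index(
    labels, scores = list(ca = sc, fe = sc, zn = sc, energy = sc),
    weights = w, thresholds = cfg$thresholds$economic)
  res$class
}

#' Classify the food security importance pillar
#'
#' Aggregates government priority list membership (included/not included),
#' traditional consumption breadth (narrow/medium/large use), nutritional
#' contribution, and nutrient affordability. Scores follow the published
#' rules: `{not_included, narrow, undetermined} -> 0`,
#' `{medium use, low} -> 1`, `{included, extensive use, high} -> 3`; the
#' medium nutrition/affordability label scores 2. With
#' `cfg$invert_affordability` the affordability scores are reversed so that
#' low cost scores 3, matching that variable's priority annotation.
#'
#' @param labels Named character vector with entries `gov_list`,
#'   `traditional`, `nutrition`, `affordability`.
#' @param cfg Run configuration.
#' @return List with `pillar`, `label`, `decision_index`.
#' @export
classify_food_security <- function(labels, cfg = default_config()) {
  stopifnot(setequal(names(labels),
                     c("gov_list", "traditional", "nutrition",
                       "affordability")))
  aff <- cfg$scores$affordability
  if (isTRUE(cfg$invert_affordability)) {
    inv <- aff
    inv[["low"]] <- aff[["high"]]
    inv[["high"]] <- aff[["low"]]
    aff <- inv
  }
  res <- aggregate_decision_index(
    labels,
    scores = list(gov_list = cfg$scores$gov_list,
                  traditional = cfg$scores$traditional,
                  nutrition = cfg$scores$nutrition,
                  affordability = aff),
    weights = cfg$weights$food_security,
    thresholds = cfg$thresholds$food_security)
  list(pillar = "food_security", label = res$class,
       decision_index = res$decision_index)
}

#' Enumerate the full rule table of a pillar
#'
#' Expands the Cartesian product of the pillar's label sets (256 rows for
#' economic benefits: four variables with four labels each; 96 for food
#' security: 2 x 3 x 4 x 4) and classifies every combination.
#'
#' @param pillar `"economic"` or `"food"`.
#' @param cfg Run configuration.
#' @return `data.frame` with one column per variable plus `decision_index`
#'   and `class`.
#' @export
enumerate_rule_table <- function(pillar = c("economic", "food"),
                                 cfg = default_config()) {
  pillar <- match.arg(pillar)
  if (pillar == "economic") {
    four <- c("undetermined", "low", "medium", "high")
    grid <- expand.grid(lafay = four, yield = four, income = four,
                        coverage = c("undetermined", "narrow", "medium",
                                     "large"),
                        stringsAsFactors = FALSE)
    cl <- lapply(seq_len(nrow(grid)), function(i)
      classify_economic(unlist(grid[i, ]), cfg))
  } else {
    four <- c("undetermined", "low", "medium", "high")
    grid <- expand.grid(gov_list = c("not_included", "included"),
                        traditional = c("narrow", "medium", "large"),
                        nutrition = four, affordability = four,
                        stringsAsFactors = FALSE)
    cl <- lapply(seq_len(nrow(grid)), function(i)
      classify_food_security(unlist(grid[i, ]), cfg))
  }
  grid$decision_index <- vapply(cl, `[[`, numeric(1), "decision_index")
  grid$class <- vapply(cl, `[[`, character(1), "label")
  grid
}
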