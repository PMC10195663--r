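# Final priority rule: combine the four pillar labels on an ordinal scale,
# assign high/medium/low, and map the class to a crisp 0-100 value via the
# centroid of its output Gaussian.

#' Ordinal level of a pillar label
#'
#' Maps every pillar label onto `{0, 1, 2, 3}` (undetermined, low, medium,
#' high). Geographic: distant 1, close 2, local 3. Vulnerability: not
#' evaluated 0, minor concern 1, threatened 3 (the merged scale has no medium
#' label). Economic and food security use their own class names directly.
#'
#' @param label Pillar label.
#' @param pillar One of `"geographic"`, `"vulnerability"`, `"economic"`,
#'   `"food_security"`.
#' @return Integer level 0-3.
#' @export
ordinal_level <- function(label, pillar) {
  maps <- list(
    geographic = c(undetermined = 0, distant = 1, close = 2, local = 3),
    vulnerability = c(not_evaluated = 0, minor_concern = 1, threatened = 3),
    economic = c(undetermined = 0, low = 1, medium = 2, high = 3),
    food_security = c(undetermined = 0, low = 1, medium = 2, high = 3)
  )
  m <- maps[[match.arg(pillar, names(maps))]]
  if (!label %in% names(m))
    stop("unknown label '", label, "' for pillar ", pillar)
  unname(m[[label]])
}

#' Final priority class from the four pillar levels
#'
#' High priority when at least 3 of the 4 pillars sit at the high level;
#' otherwise medium when the geographic origin is at least medium and at
#' least 2 of the other three pillars are at or above medium; otherwise low.
#'
#' @param geographic,vulnerability,economic,food_security Ordinal levels 0-3
#'   (see [ordinal_level()]).
#' @return `"high"`, `"medium"`, or `"low"`.
#' @export
final_class <- function(geographic, vulnerability, economic, food_security) {
  lv <- c(geographic, vulnerability, economic, food_security)
  stopifnot(length(lv) == 4L, all(lv %in% 0:3))
  if (sum(lv == 3) >= 3) return("high")
  if (geographic >= 2 && sum(lv[-1] >= 2) >= 2) return("medium")
  "low"
}

#' Crisp priority value of a class
#'
#' Centroid defuzzification of the class's output Gaussian at full
#' activation; by symmetry the value equals the Gaussian center (15 low,
#' 55 medium, 90 high under the default parameters) within one grid step.
#'
#' @param class `"low"`, `"medium"`, or `"high"`.
#' @param cfg Run configuration (holds the output Gaussians and universe).
#' @param grades Optional named activation grades per class for blended
#'   activation; default crisp single-class activation.
#' @return Value in `[0, 100]`.
#' @export
priority_value <- function(class, cfg = default_config(), grades = NULL) {
  sets <- build_sets(cfg$membership$priority_index)
  u <- do.call(universe_spec, cfg$universe)
  if (is.null(grades)) {
    class <- match.arg(class, names(sets))
    acts <- list(list(grade = 1, f = sets[[class]]$f))
  } else {
    acts <- lapply(names(grades), function(lb)
      list(grade = grades[[lb]], f = sets[[lb]]$f))
  }
  centroid_defuzzify(acts, u)
}

#' Rank a classified dataset
#'
#' Combines per-species pillar labels into final classes and crisp priority
#' values, and returns the list sorted by priority value (descending), then
#' by the sum of the two decision indices (descending), then by species id.
#'
#' @param pillar_table `data.frame` with columns `species_id`, `group`,
#'   `geographic`, `vulnerability`, `economic`, `food_security`,
#'   `economic_index`, `food_index`, and uncertainty tag columns
#'   (`tag_geographic`, `tag_economic`, `tag_food_security`).
#' @param cfg Run configuration.
#' @return `data.frame` of ranked results with `final_class` and
#'   `priority_value`.
#' @export
rank_all <- function(pillar_table, cfg = default_config()) {
  if (anyDuplicated(pillar_table$species_id))
    stop("duplicate species ids in pillar table")
  lv <- function(p) vapply(seq_len(nrow(pillar_table)), function(i)
    ordinal_level(pillar_table[[p]][i], p), numeric(1))
  g <- lv("geographic"); v <- lv("vulnerability")
  e <- lv("economic"); fsec <- lv("food_security")
  cls <- vapply(seq_len(nrow(pillar_table)), function(i)
    final_class(g[i], v[i], e[i], fsec[i]), character(1))
  # the three class centroids are fixed by config; compute each once
  vals <- vapply(c(low = "low", medium = "medium", high = "high"),
                 priority_value, numeric(1), cfg = cfg)
  out <- pillar_table
  out$final_class <- cls
  out$priority_value <- vals[cls]
  idx_sum <- ifelse(is.na(out$economic_index), 0, out$economic_index) +
    ifelse(is.na(out$food_index), 0, out$food_index)
  tags <- cbind(out$tag_geographic, out$tag_economic, out$tag_food_security)
  rk <- c(reliable = 0, GP = 1, PCG = 2)
  out$uncertainty <- c("reliable", "GP", "PCG")[
    apply(matrix(rk[tags], nrow = nrow(out)), 1, max) + 1]
  ord <- order(-out$priority_value, -idx_sum, out$species_id)
  out[ord, , drop = FALSE]
}
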