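# Per-species economic and nutritional indicators. All operations propagate
# missingness (NA) rather than raising, so downstream "undetermined" handling
# is exercised; hard errors are reserved for data-integrity violations.

#' Income per hectare
#'
#' `Inc_i = (P_i * Pr_i) / A_i`: sales price (USD/t) times annual production
#' (t) over harvested area (ha), a proxy for economic efficiency per unit
#' area.
#'
#' @param price USD per tonne.
#' @param production Tonnes per year.
#' @param area Harvested hectares.
#' @return USD per hectare, or `NA` when an input is missing or area is zero.
#' @export
income <- function(price, production, area) {
  out <- price * production / area
  out[!is.na(area) & area == 0] <- NA_real_
  out
}

#' Lafay trade-balance index
#'
#' `Li = Pd_i / (Pd_i + M_i - X_i)`: production over apparent consumption
#' (production + imports - exports). Values above one indicate a net
#' exporter. The index may be negative or large when exports exceed apparent
#' supply.
#'
#' @param production,imports,exports Tonnes per year.
#' @return The ratio, or `NA` (with a warning) when the denominator is zero.
#' @export
lafay <- function(production, imports, exports) {
  den <- production + imports - exports
  zero <- !is.na(den) & den == 0
  if (any(zero)) {
    warning("lafay undefined (zero apparent consumption) for ",
            sum(zero), " record(s); returning NA")
    den[zero] <- NA_real_
  }
  production / den
}

#' Municipality coverage
#'
#' `CM_i = (M_i / TM) * 100`: percentage of the country's municipalities
#' cultivating the species, a proxy for regional spread and adaptability.
#'
#' @param municipalities Count of municipalities cultivating the species.
#' @param total_municipalities Total municipalities (configuration value).
#' @return Percentage in `[0, 100]`, `NA` propagated.
#' @export
municipality_coverage <- function(municipalities, total_municipalities) {
  stopifnot(length(total_municipalities) == 1L, total_municipalities > 0)
  bad <- !is.na(municipalities) &
    (municipalities < 0 | municipalities > total_municipalities)
  if (any(bad))
    stop("municipality count outside [0, TM] for ", sum(bad), " record(s)")
  municipalities / total_municipalities * 100
}

#' Crop yield
#'
#' `R_i = Pr_i / A_i` with multi-year production and harvested area averaged
#' before the division (the study window is 2007-2017).
#'
#' @param production Numeric vector of annual production values (t).
#' @param area Numeric vector of annual harvested areas (ha).
#' @return Tonnes per hectare, or `NA` when area data are absent or zero.
#' @export
crop_yield <- function(production, area) {
  pr <- mean(production, na.rm = TRUE)
  ar <- mean(area, na.rm = TRUE)
  if (!is.finite(pr) || !is.finite(ar) || ar == 0) return(NA_real_)
  pr / ar
}

#' Nutritional contribution to a daily micronutrient target
#'
#' Average daily contribution `AD_ij = (CD_i * M_j) / 100` (consumption in
#' g/day times content per 100 g), expressed as a percentage of the daily
#' target: `C_ij = AD_ij / MN_j * 100`.
#'
#' @param consumption Daily consumption, g/day.
#' @param content Micronutrient content per 100 g (mg, or kcal for energy).
#' @param target Daily target (mg/day, or kcal/day); must be positive.
#' @return Percent of the daily target, `NA` propagated.
#' @export
nutritional_contribution <- function(consumption, content, target) {
  if (any(!is.na(target) & target <= 0))
    stop("daily micronutrient target must be positive")
  (consumption * content / 100) / target * 100
}

#' Nutrient-price ratio (affordability)
#'
#' Consumer price of 100 g of edible portion per unit of nutrient delivered;
#' lower is more affordable.
#'
#' @param price USD per 100 g edible portion.
#' @param content Nutrient per 100 g (mg, or kcal for energy).
#' @return USD per nutrient unit; `NA` when the nutrient is absent
#'   (affordability undefined).
#' @export
nutrient_price_ratio <- function(price, content) {
  out <- price / content
  out[!is.na(content) & content == 0] <- NA_real_
  out
}

#' Range normalization onto \[1, 100\]
#'
#' Affine map `x' = 1 + 99 (x - min) / (max - min)`; the observed (or
#' supplied) minimum maps to 1 and maximum to 100. Preserves ordering and
#' ratios of differences. `NA`s pass through.
#'
#' @param x Numeric vector.
#' @param lo,hi Optional fixed bounds; default observed finite range of `x`.
#' @return Normalized vector on `[1, 100]` (clamped when fixed bounds are
#'   narrower than the data).
#' @export
range_normalize <- function(x, lo = NULL, hi = NULL) {
  obs <- x[is.finite(x)]
  if (is.null(lo)) lo <- suppressWarnings(min(obs))
  if (is.null(hi)) hi <- suppressWarnings(max(obs))
  if (!is.finite(lo) || !is.finite(hi)) return(rep(NA_real_, length(x)))
  if (hi <= lo) {
    warning("degenerate range in range_normalize; mapping all values to 1")
    out <- ifelse(is.na(x), NA_real_, 1)
    return(out)
  }
  pmin(pmax(1 + 99 * (x - lo) / (hi - lo), 1), 100)
}

#' Optimal univariate k-means by dynamic programming
#'
#' Exact 1-D k-means: clusters are contiguous in sorted order, so the
#' globally optimal partition (minimum total within-cluster sum of squares)
#' is found by dynamic programming over split points. Deterministic; no
#' seed. Used to calibrate label boundaries for new variables.
#'
#' @param x Numeric vector, at least `k` distinct finite values.
#' @param k Number of clusters.
#' @return List with `assignments` (cluster rank per value of `x`, 1 = lowest
#'   centroid), `centroids` (increasing), and `withinss` (total within-cluster
#'   sum of squares).
#' @export
ckmeans_1d <- function(x, k = 3L) {
  stopifnot(is.numeric(x), length(k) == 1L, k >= 1L)
  if (any(!is.finite(x))) stop("ckmeans_1d requires finite values")
  if (length(unique(x)) < k)
    stop("ckmeans_1d needs at least k distinct values")
  ord <- order(x)
  xs <- x[ord]
  n <- length(xs)
  cs <- cumsum(xs)
  cs2 <- cumsum(xs^2)
  # within-SS of sorted segment (i, j]
  seg <- function(i, j) {
    s <- cs[j] - if (i > 0) cs[i] else 0
    s2 <- cs2[j] - if (i > 0) cs2[i] else 0
    s2 - s^2 / (j - i)
  }
  D <- matrix(Inf, nrow = k, ncol = n)
  B <- matrix(0L, nrow = k, ncol = n)   # last split: start index of cluster q
  for (j in seq_len(n)) D[1, j] <- seg(0L, j)
  if (k > 1) {
    for (q in 2:k) {
      for (j in q:n) {
        best <- Inf; arg <- q - 1L
        for (i in (q - 1L):(j - 1L)) {
          v <- D[q - 1L, i] + seg(i, j)
          if (v < best) { best <- v; arg <- i }
        }
        D[q, j] <- best
        B[q, j] <- arg
      }
    }
  }
  bounds <- integer(k + 1L)
  bounds[k + 1L] <- n
  if (k > 1) for (q in k:2) bounds[q] <- B[q, bounds[q + 1L]]
  assign_sorted <- integer(n)
  centroids <- numeric(k)
  for (q in seq_len(k)) {
    idx <- (bounds[q] + 1L):bounds[q + 1L]
    assign_sorted[idx] <- q
    centroids[q] <- mean(xs[idx])
  }
  assignments <- integer(n)
  assignments[ord] <- assign_sorted
  list(assignments = assignments, centroids = centroids, withinss = D[k, n])
}

#' Derive trapezoid label boundaries from 1-D k-means clusters
#'
#' Calibration path for new variables: cluster normalized values into `k = 3`
#' groups and place low/medium/high trapezoids with plateaus spanning each
#' cluster's range and ramps meeting at the midpoints between adjacent
#' cluster edges. Default runs of the index use the shipped membership
#' parameters verbatim; this helper supports extending the index to new
#' variables.
#'
#' @param x Normalized values on the universe.
#' @param labels Labels for the increasing clusters.
#' @param u Universe bounds for the outer ramps.
#' @return Named list of `labeled_fuzzy_set`s.
#' @export
calibrate_trapezoids <- function(x, labels = c("low", "medium", "high"),
                                 u = universe_spec()) {
  k <- length(labels)
  cl <- ckmeans_1d(x[is.finite(x)], k)
  pr <- c("low", "middle", "high")[round(seq(1, 3, length.out = k))]
  sets <- vector("list", k)
  for (q in seq_len(k)) {
    vals <- x[is.finite(x)][cl$assignments == q]
    m <- min(vals); n <- max(vals)
    a <- if (q == 1) u$lower else {
      prev <- max(x[is.finite(x)][cl$assignments == q - 1L])
      (prev + m) / 2
    }
    b <- if (q == k) u$upper else {
      nxt <- min(x[is.finite(x)][cl$assignments == q + 1L])
      (n + nxt) / 2
    }
    sets[[q]] <- fuzzy_set(labels[q], mf_trapezoid(min(a, m), m, n, max(b, n)),
                           priority = pr[q])
  }
  names(sets) <- labels
  sets
}
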