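#' Universe specification for fuzzy membership functions
#'
#' All variables in the prioritization index live on a common data universe,
#' by default `[0, 100]`. The resolution is the grid step used for numeric
#' centroid defuzzification.
#'
#' @param lower,upper Universe bounds; `lower < upper`.
#' @param resolution Positive grid step for the centroid integral.
#' @return An object of class `universe_spec`.
#' @export
#' @examples
#' universe_spec()
universe_spec <- function(lower = 0, upper = 100, resolution = 0.01) {
  stopifnot(is.numeric(lower), is.numeric(upper), is.numeric(resolution),
            length(lower) == 1L, length(upper) == 1L, length(resolution) == 1L,
            is.finite(lower), is.finite(upper), is.finite(resolution))
  if (lower >= upper) stop("universe lower bound must be below upper bound")
  if (resolution <= 0) stop("universe resolution must be positive")
  structure(list(lower = lower, upper = upper, resolution = resolution),
            class = "universe_spec")
}

#' Membership function constructors
#'
#' Three shapes cover every variable in the index: a singleton for
#' categorical inputs (an indicator at location `a`, with a small numeric
#' tolerance standing in for the near-degenerate Gaussian often drawn for
#' singletons), a trapezoid `a <= m <= n <= b` for continuous inputs (grade 1
#' on the plateau `[m, n]`, linear ramps on `[a, m]` and `[n, b]`, 0 outside
#' the support `[a, b]`), and a Gaussian `exp(-(x - mu)^2 / (2 sigma^2))` for
#' the output priority classes.
#'
#' @param a Singleton location, or trapezoid bottom-left.
#' @param tol Singleton tolerance: grade is 1 iff `|x - a| <= tol`.
#' @param m,n Trapezoid plateau (top-left, top-right).
#' @param b Trapezoid bottom-right.
#' @param mu,sigma Gaussian center and width (`sigma > 0`).
#' @return A `membership_function` object.
#' @name membership
#' @export
#' @examples
#' eval_membership(57.5, mf_trapezoid(50, 65, 70, 85))
mf_singleton <- function(a, tol = 0.001) {
  stopifnot(is.numeric(a), length(a) == 1L, is.finite(a),
            is.numeric(tol), length(tol) == 1L, tol > 0)
  structure(list(shape = "singleton", a = a, tol = tol),
            class = "membership_function")
}

#' @rdname membership
#' @export
mf_trapezoid <- function(a, m, n, b) {
  p <- c(a = a, m = m, n = n, b = b)
  stopifnot(is.numeric(p), length(p) == 4L, all(is.finite(p)))
  if (!(a <= m && m <= n && n <= b))
    stop("trapezoid requires a <= m <= n <= b, got (",
         paste(p, collapse = ", "), ")")
  structure(list(shape = "trapezoid", a = a, m = m, n = n, b = b),
            class = "membership_function")
}

#' @rdname membership
#' @export
mf_gaussian <- function(mu, sigma) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu),
            is.numeric(sigma), length(sigma) == 1L, is.finite(sigma))
  if (sigma <= 0) stop("gaussian requires sigma > 0")
  structure(list(shape = "gaussian", mu = mu, sigma = sigma),
            class = "membership_function")
}

#' @export
print.membership_function <- function(x, ...) {
  pars <- x[setdiff(names(x), "shape")]
  cat(sprintf("<%s: %s>\n", x$shape,
              paste(names(pars), unlist(pars), sep = "=", collapse = ", ")))
  invisible(x)
}

#' Evaluate a membership function
#'
#' @param x Numeric vector of crisp values (finite).
#' @param f A `membership_function`.
#' @return Grades in `[0, 1]`, same length as `x`.
#' @export
eval_membership <- function(x, f) {
  stopifnot(inherits(f, "membership_function"), is.numeric(x))
  if (any(!is.finite(x))) stop("eval_membership requires finite x")
  switch(f$shape,
    singleton = as.numeric(abs(x - f$a) <= f$tol),
    gaussian  = exp(-(x - f$mu)^2 / (2 * f$sigma^2)),
    trapezoid = {
      g <- numeric(length(x))
      g[x >= f$m & x <= f$n] <- 1
      # ramps; degenerate ramps (a == m or n == b) behave as steps
      up <- x > f$a & x < f$m
      if (f$m > f$a) g[up] <- (x[up] - f$a) / (f$m - f$a)
      dn <- x > f$n & x < f$b
      if (f$b > f$n) g[dn] <- (f$b - x[dn]) / (f$b - f$n)
      g
    },
    stop("unknown membership shape: ", f$shape)
  )
}

#' Labeled fuzzy set
#'
#' A membership function tagged with a class label and the priority level the
#' label carries (used for tie-breaking during fuzzification and for the
#' ordinal scale of the final ranking rule).
#'
#' @param label Class label, unique within a variable's set list.
#' @param f A `membership_function`.
#' @param priority One of `"high"`, `"middle"`, `"low"`, `"undetermined"`.
#' @return A `labeled_fuzzy_set`.
#' @export
fuzzy_set <- function(label, f, priority = "undetermined") {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label),
            inherits(f, "membership_function"))
  priority <- match.arg(priority, c("high", "middle", "low", "undetermined"))
  structure(list(label = label, priority = priority, f = f),
            class = "labeled_fuzzy_set")
}

.priority_rank <- c(undetermined = 0, low = 1, middle = 2, high = 3)

#' Fuzzify a crisp value against a list of labeled sets
#'
#' Assigns the label with maximal membership grade. Ties are broken toward
#' the label with the higher priority annotation (conservative toward
#' flagging a species for attention), then toward the later set in the list.
#' If every grade is zero the assignment is `"undetermined"` with grade 0.
#'
#' @param x Single finite numeric value on the variable's normalized scale.
#' @param sets Non-empty list of `labeled_fuzzy_set` objects.
#' @return A list with `label`, `grade`, and the named vector `all_grades`.
#' @export
fuzzify <- function(x, sets) {
  stopifnot(length(sets) >= 1L, is.numeric(x), length(x) == 1L, is.finite(x))
  labels <- vapply(sets, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("duplicate labels in fuzzy set list")
  grades <- vapply(sets, function(s) eval_membership(x, s$f), numeric(1))
  names(grades) <- labels
  if (all(grades == 0))
    return(list(label = "undetermined", grade = 0, all_grades = grades))
  pr <- .priority_rank[vapply(sets, `[[`, character(1), "priority")]
  best <- which(grades == max(grades))
  winner <- best[which.max(pr[best])]
  list(label = unname(labels[winner]), grade = unname(grades[winner]),
       all_grades = grades)
}

#' Centroid defuzzification
#'
#' Aggregates activated output sets by clipping each membership function at
#' its activation grade (min) and taking the pointwise maximum, then returns
#' the center of mass of the aggregate over the universe, on a fixed grid.
#'
#' @param activations Named list: each element a list with `grade` in `[0,1]`
#'   and `f`, a `membership_function`.
#' @param u A `universe_spec`.
#' @return Crisp value in `[lower, upper]`.
#' @export
#' @examples
#' centroid_defuzzify(list(high = list(grade = 1, f = mf_gaussian(90, 5))))
centroid_defuzzify <- function(activations, u = universe_spec()) {
  stopifnot(inherits(u, "universe_spec"), length(activations) >= 1L)
  grades <- vapply(activations, `[[`, numeric(1), "grade")
  if (all(grades <= 0)) stop("no activated output class")
  xs <- seq(u$lower, u$upper, by = u$resolution)
  agg <- numeric(length(xs))
  for (act in activations) {
    if (act$grade <= 0) next
    agg <- pmax(agg, pmin(act$grade, eval_membership(xs, act$f)))
  }
  sum(xs * agg) / sum(agg)
}
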