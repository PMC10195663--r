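test_that("trapezoid membership: plateau, ramps, support", {
  f <- mf_trapezoid(50, 65, 70, 85)
  expect_equal(eval_membership(65, f), 1)
  expect_equal(eval_membership(c(65, 67, 70), f), c(1, 1, 1))
  expect_equal(eval_membership(57.5, f), 0.5)   # midpoint of the up ramp
  expect_equal(eval_membership(77.5, f), 0.5)   # midpoint of the down ramp
  expect_equal(eval_membership(c(49, 50, 85, 90), f), c(0, 0, 0, 0))
  # degenerate ramp behaves as a step
  g <- mf_trapezoid(10, 10, 20, 30)
  expect_equal(eval_membership(10, g), 1)
  expect_error(mf_trapezoid(10, 5, 20, 30), "a <= m")
})

test_that("gaussian and singleton membership evaluate per their definitions", {
  expect_equal(eval_membership(95, mf_gaussian(90, 5)), exp(-0.5))
  expect_equal(eval_membership(90, mf_gaussian(90, 5)), 1)
  expect_error(mf_gaussian(90, 0), "sigma")
  s <- mf_singleton(70)
  expect_equal(eval_membership(70, s), 1)
  expect_equal(eval_membership(70.0005, s), 1)  # within tolerance
  expect_equal(eval_membership(69, s), 0)
  expect_error(eval_membership(NaN, s), "finite")
})

test_that("trapezoid grades are in [0,1] and monotone on the ramps", {
  set.seed(42)
  for (rep in 1:50) {
    p <- sort(runif(4, 0, 100))
    f <- mf_trapezoid(p[1], p[2], p[3], p[4])
    xs <- seq(0, 100, length.out = 401)
    g <- eval_membership(xs, f)
    expect_true(all(g >= 0 & g <= 1))
    up <- xs >= p[1] & xs <= p[2]
    dn <- xs >= p[3] & xs <= p[4]
    expect_true(all(diff(g[up]) >= -1e-12))
    expect_true(all(diff(g[dn]) <= 1e-12))
    expect_true(all(g[xs >= p[2] & xs <= p[3]] == 1))
  }
})

test_that("fuzzify assigns max-grade label with priority tie-break", {
  geo <- list(fuzzy_set("distant", mf_singleton(0), "low"),
              fuzzy_set("close", mf_singleton(45), "middle"),
              fuzzy_set("local", mf_singleton(70), "high"))
  out <- fuzzify(70, geo)
  expect_equal(out$label, "local")
  expect_equal(out$grade, 1)
  # empty support -> undetermined with grade 0
  expect_equal(fuzzify(2, geo)$label, "undetermined")
  expect_equal(fuzzify(2, geo)$grade, 0)
  # equal 0.5 grades on a shared ramp crossing: higher priority wins
  low <- fuzzy_set("low", mf_trapezoid(0, 10, 20, 40), "low")
  med <- fuzzy_set("medium", mf_trapezoid(20, 40, 60, 80), "middle")
  x <- 30  # descending ramp of low and ascending ramp of medium both 0.5
  expect_equal(eval_membership(x, low$f), 0.5)
  expect_equal(eval_membership(x, med$f), 0.5)
  expect_equal(fuzzify(x, list(low, med))$label, "medium")
})

test_that("fuzzify is unchanged by adding an everywhere-zero set", {
  sets <- list(fuzzy_set("low", mf_trapezoid(0, 10, 20, 40), "low"),
               fuzzy_set("high", mf_trapezoid(30, 50, 100, 100), "high"))
  zero <- fuzzy_set("ghost", mf_singleton(-500), "high")
  for (x in c(5, 15, 33, 60, 99)) {
    a <- fuzzify(x, sets)
    b <- fuzzify(x, c(sets, list(zero)))
    expect_equal(a$label, b$label)
    expect_equal(a$grade, b$grade)
  }
})

test_that("centroid defuzzification recovers symmetric centers and mixtures", {
  u <- universe_spec()
  one <- function(mu) centroid_defuzzify(
    list(x = list(grade = 1, f = mf_gaussian(mu, 5))), u)
  # closed-form mean of a normal restricted to the universe: the exact
  # centroid of a Gaussian set clipped at the domain bounds
  tmean <- function(mu, s, lo = 0, hi = 100) {
    a <- (lo - mu) / s; b <- (hi - mu) / s
    mu + s * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  }
  expect_lt(abs(one(50) - 50), u$resolution)   # symmetric within the domain
  expect_lt(abs(one(90) - tmean(90, 5)), u$resolution)
  expect_lt(abs(one(15) - tmean(15, 5)), u$resolution)
  # boundary truncation shifts centers by well under one universe unit
  expect_lt(abs(one(90) - 90), 0.5)
  expect_lt(abs(one(15) - 15), 0.5)
  # equal-mass mixture symmetric within the universe: centroid at the center
  sym <- centroid_defuzzify(list(
    lo = list(grade = 1, f = mf_gaussian(30, 5)),
    hi = list(grade = 1, f = mf_gaussian(70, 5))), u)
  expect_equal(sym, 50, tolerance = u$resolution)
  # mu = 15 / mu = 90 pair: near the 52.5 midpoint, but the universe truncates
  # the upper Gaussian at 100 (2 sigma); check against adaptive quadrature
  two <- centroid_defuzzify(list(
    lo = list(grade = 1, f = mf_gaussian(15, 5)),
    hi = list(grade = 1, f = mf_gaussian(90, 5))), u)
  mix <- function(x) pmax(exp(-(x - 15)^2 / 50), exp(-(x - 90)^2 / 50))
  oracle <- stats::integrate(function(x) x * mix(x), 0, 100)$value /
    stats::integrate(mix, 0, 100)$value
  expect_equal(two, oracle, tolerance = 0.01)
  expect_equal(two, 52.5, tolerance = 0.6)  # symmetry argument, pre-truncation
  expect_error(centroid_defuzzify(
    list(x = list(grade = 0, f = mf_gaussian(50, 5))), u),
    "no activated output class")
})

test_that("universe specification rejects degenerate parameters", {
  expect_error(universe_spec(100, 0), "lower")
  expect_error(universe_spec(0, 100, 0), "resolution")
})
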