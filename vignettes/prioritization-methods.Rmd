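---
title: "Methods: a four-pillar fuzzy prioritization index for PGRFA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a four-pillar fuzzy prioritization index for PGRFA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agroprior)
```

## The problem and the model

A national plant germplasm bank conserves far more species than it can
research, and candidate species outside the bank compete for the same
budget. `agroprior` turns heterogeneous evidence — regions of diversity,
red-list status, agricultural statistics, and food-composition data — into
a single high/medium/low research-priority class per species plus a crisp
0–100 value, through a Mamdani-style fuzzy inference system.

Every variable lives on a data universe $X = [0, 100]$. Categorical
variables (origin class, vulnerability class, government-list membership)
are encoded by **singleton** membership functions: indicators at a location
$a$, evaluated with a small numerical tolerance (0.001) that plays the role
of the near-degenerate Gaussian such singletons are usually drawn with.
Continuous variables use **trapezoids** $(a, m, n, b)$: grade 0 outside the
support $[a, b]$, linear ramps, grade 1 on the plateau $[m, n]$. Output
priority classes use **Gaussians** $\exp(-(x-\mu)^2 / 2\sigma^2)$ with
$\mu = 15, 55, 90$ and $\sigma = 5$, collapsed to a crisp value by centroid
defuzzification (clip each activated set at its grade, take the pointwise
maximum, return the center of mass on a fixed grid).

Fuzzification assigns the label of maximal grade. Where two sets tie — the
shipped trapezoids deliberately overlap on their ramps — the label carrying
the *higher* priority annotation wins. This tie-break is our choice, made
conservatively so that a borderline species is flagged for attention rather
than dismissed; the alternative (lower label wins) changes nothing for
values sampled on plateaus and only reorders exact ramp crossings.

## Indicators and normalization

The economic pillar uses four indicators:

* **Income per hectare** $Inc_i = (P_i \times Pr_i)/A_i$ (USD/ha), from the
  latest year with complete price, production, and area data. Incomes span
  several orders of magnitude, so the pipeline takes $\log_{10}$ before
  range normalization.
* **Lafay index** $L_i = Pd_i/(Pd_i + M_i - X_i)$, production over apparent
  consumption, with flows averaged over the same multi-year window as
  yield. Values below 0 (exports exceeding apparent supply) are clipped to
  0 before normalization, because the membership supports begin at the
  universe origin. A zero denominator yields a missing value with a
  warning, not an error.
* **Municipality coverage** $CM_i = (M_i/TM) \times 100$. The total
  municipality count $TM$ is a configuration value (default 1122), never a
  constant in code.
* **Yield** $R_i = Pr_i/A_i$ with production and harvested area averaged
  over the reporting window (the reference window is 2007–2017). Yields
  differ in scale across the nine FAO food categories, so range
  normalization is applied *within* each category.

Range normalization maps observed (or configured) bounds onto $[1, 100]$:
$x' = 1 + 99\,(x - \min)/(\max - \min)$. Bounds default to the observed
finite range of the data, which is how a one-off national analysis behaves;
fixing them in the configuration makes runs comparable across datasets and
is what the synthetic generator does.

The food-security pillar combines government-list membership, traditional
consumption, nutritional contribution, and affordability. Nutritional
contribution is computed per micronutrient $j \in \{$calcium, iron, zinc,
energy$\}$: $AD_{ij} = CD_i \times M_j / 100$ and
$C_{ij} = AD_{ij}/MN_j \times 100$, the percent of the daily target $MN_j$
met by the species' daily consumption. Affordability is the consumer price
of 100 g of edible portion per nutrient unit, normalized per micronutrient.
Both blocks are themselves four-input rule bases (one label per
micronutrient, equal weights) whose summary label feeds the pillar. Daily
targets are configuration values (defaults: 1000 mg Ca, 11 mg Fe, 5 mg Zn,
1350 kcal — replace them with the national dietary reference for a real
run).

Traditional consumption counts the cultural regions (out of 11) where a
species matters for food tradition. The shipped trapezoids for this
variable are kept verbatim in the configuration, but they are mutually
inconsistent with the stated count rule (a count of 2, range-normalized,
would land on the "large" ramp), so the pipeline labels this variable
directly by the count rule: narrow 1–3, medium 4–6, large 7–11. This is
the one variable classified by explicit breaks rather than fuzzification.

## Decision-index aggregation

Each four-variable pillar maps labels to ordinal scores: economic uses
0/1/2/3 for undetermined/low/medium/high (coverage: undetermined/narrow/
medium/large); food security uses the published sparse scores —
$\{$not included, narrow use, undetermined$\} \to 0$, $\{$medium use,
low$\} \to 1$, $\{$included, extensive use, high$\} \to 3$ — with the
medium nutrition/affordability label scored 2 by analogy with the economic
scale (the source rules never state it; the choice is logged).

The decision index is $ID = \sum_z S_z w_z / 4$ with $\sum w_z = 1$ and
default $w_z = 0.25$. The published formula multiplies by 100 while its
thresholds live on $[0, 1]$; we resolve the inconsistency by dividing the
weighted score (range $[0, 3]$) by 4, the unique simple scaling under
which every homogeneous combination lands in its namesake interval
(all-low $\to 0.25$, all-medium $\to 0.5$, all-high $\to 0.75$), and treat
the $\times 100$ as display scale. Classes are assigned by half-open
intervals that close the small gaps in the printed thresholds: economic
$[0, 0.25)$ undetermined, $[0.25, 0.46)$ low, $[0.46, 0.65)$ medium,
$[0.65, 1]$ high; food security's medium opens at 0.45, exactly as
printed. Enumerating the label products gives $4^4 = 256$ economic rules
and $2 \times 3 \times 4 \times 4 = 96$ food-security rules, every one of
which is monotone: raising any single variable's score never lowers the
class (verified exhaustively in the tests).

Affordability's priority annotation runs opposite to its score: cheap
nutrients are annotated high-priority, yet the literal scoring rule gives
the "low" label a score of 1. The default follows the literal rule; the
`invert_affordability` configuration switch applies the annotation instead
(low cost scores 3). The default was chosen for fidelity, not preference,
and the switch makes the alternative a one-line change.

## Imputation and uncertainty

Species in the bank (BGVCOL group) with a fully undetermined geographic,
economic, or food-security pillar borrow data from a donor: first choice is
the gene pool (same genus, or an explicit crop-group mapping in the
configuration); fallback is the provisional crop group (same FAO food
category). Among eligible donors the *worst case* wins — the donor whose
own data yield the lowest decision index (lowest origin class for the
geographic pillar), ties broken lexicographically — operationalizing the
stated purpose of avoiding bias toward inflated priority. Only variables
whose raw data are missing are filled; values a species already has are
never overwritten, and a species whose own complete data merely *score*
undetermined is left alone. Vulnerability is never imputed (threat status
does not transfer between congeners), and species outside the bank (NCB)
are never imputed. Every pillar carries a tag: `reliable` (own data, or
left undetermined), `GP`, or `PCG`; the tags partition the species list
per pillar, and an audit table records every recipient/donor/path triple.
Asserted origins (e.g. a species whose origin is known from expert
judgment rather than the region table) are per-species configuration
overrides, applied before imputation.

## Final ranking

Pillar labels map onto ordinal levels 0–3 (geographic: distant 1, close 2,
local 3; vulnerability: not evaluated 0, minor concern 1, threatened 3 —
the merged scale has no medium). The final class is high when at least 3 of
4 pillars are at level 3; otherwise medium when the geographic level is ≥ 2
and at least 2 of the other three pillars are ≥ 2 ("at least medium"
requires level 2, which for vulnerability only "threatened" satisfies);
otherwise low. The class's output Gaussian at full activation is
defuzzified to the priority value. Within a class, ties in the ranked
output are broken by the sum of the two decision indices, then species id.
A blend mode (activating each output Gaussian by a continuous degree of
rule satisfaction) exists but is off by default: the source procedure's
mechanism for intermediate values is unstated, so the default stays crisp.

## Numerical choices

* Centroid integration uses a fixed grid, step 0.01 on $[0, 100]$.
* The universe clips Gaussian tails: the high output set ($\mu = 90$,
  $\sigma = 5$) loses its mass above 100, so its exact centroid is the
  truncated-normal mean 89.724 rather than 90 (the low set: 15.022). The
  grid centroid reproduces the truncated value to one grid step; tests
  check against the closed form, and reported priority values inherit the
  shift (89.72/55/15.02).
* Singleton evaluation is an indicator with tolerance `0.001` rather than a
  narrow Gaussian: identical behavior for categorical inputs mapped onto
  the singleton location, and numerically robust.
* Degenerate trapezoid ramps ($a = m$ or $n = b$) evaluate as steps; the
  shipped medium Lafay set has a single-point plateau ($m = n = 20.8$).
* A value with zero grade in every set is labeled `undetermined` with
  grade 0 — this happens in the gaps the shipped supports leave near the
  universe origin and is the intended "no decision" behavior.
* `ckmeans_1d` is an exact dynamic program over split points (1-D k-means
  clusters are contiguous in sorted order), deterministic with no seed. It
  is the calibration path for deriving label boundaries on *new* variables
  (`calibrate_trapezoids`); default runs use the shipped membership
  parameters verbatim, since the published parameterization is the ground
  truth being reproduced.
* All indicator arithmetic propagates missing values instead of raising;
  hard errors are reserved for integrity violations (counts exceeding
  totals, unknown vocabulary entries, non-positive targets).

## The synthetic generator

`generate_synthetic()` emulates the structure the index consumes, not any
real agriculture: a registry with genus structure (sizes skewed so a few
genera dominate, as in real collections) and FAO categories, and one
planted label per variable. Raw values are sampled from inside the planted
label's membership plateau, *inverted through the same normalization the
pipeline applies*, using fixed normalization bounds written into the
generator's configuration (income $\log_{10}$ bounds $[0, \log_{10} 5
\times 10^4]$; Lafay $[0, 5.28]$, matching the observed range of the
reference analysis; yield $[0, 20]$ t/ha per FAO group; contribution and
affordability bounds scaled by the daily targets so the four per-nutrient
labels coincide). Plateau sampling makes recovery deterministic: with no
missingness the pipeline recovers 100% of planted variable labels, pillar
labels, and final classes, which is what the recovery tests assert. A
`hard_mode` flag samples from full supports instead, exercising ramps and
tie-breaking, at the cost of exact recoverability.

Missingness is applied per pillar to bank species at configurable rates
(defaults 0.62 economic, 0.73 food security, matching the study conditions
the index was designed under). With `ensure_donors`, blanking is restricted
to multi-species genera and one member per genus always stays complete, so
every blanked species has a gene-pool donor; the empirical rates stay
within a few percentage points of the request (checked at $n = 345$).

What passing these tests does *not* show: the generator plants one shared
label across a species' four micronutrients (a single price/content vector
cannot hit four independent affordability labels), samples no conflicting
multi-year trends, and draws labels independently across variables, whereas
real agricultural data are correlated, ramp-ambiguous, and vintage-mixed.
Recovery results therefore validate the machinery — normalization,
fuzzification, rule aggregation, imputation, ranking — not the index's
ecological or economic validity on real data.

## Problem sizes and determinism

The test suite runs the full pipeline at $n = 345$ (the reference study's
size: 275 bank + 70 external species) for the recovery and imputation
checks, smaller $n$ for structural tests, 200 random instances ($n \le
25$) for the k-means oracle, and exhaustive enumeration for the 256 + 96
rule tables and all $4^4$ final-rule combinations. Everything downstream of
the generator is deterministic given inputs; byte-identical outputs on
repeated runs are asserted in the io tests.

## Known limitations

* The region vocabulary ships as published, deduplicated to 25 unique
  names; classification only depends on the local/close subsets, so the
  count discrepancy is cosmetic.
* Price vintages are taken as given (consumer prices and production years
  need not match), and there is no currency conversion or inflation
  adjustment.
* The crisp final rule yields exactly three priority values; a continuum on
  0–100 requires the optional blend mode.
* Imputation copies labels within a pillar wholesale from one donor; it is
  not statistical imputation and deliberately ignores phylogenetic
  distance beyond genus/category membership.
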