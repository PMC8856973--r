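---
title: "Measuring wealth-related concentration of NCD risk factors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring wealth-related concentration of NCD risk factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(concx)
```

## The model

The package measures how exposure to a behavioural NCD risk factor is
distributed across ordered wealth categories. Both variables are ordered
categorical systems with cumulative percentage weights: four wealth
categories (`poor < rich < richer < richest`) and four exposure levels
(`relatively_exposed < exposed < more_exposed < most_exposed`), each rank
`i` of `k = 4` carrying the cumulative weight `25·i` percent. The equal
25-point assignment is not an estimate — it is the definition of the
category system, the four-way analogue of quintile shares, and it is what a
weighted-quartile collapse of a continuous wealth score produces by
construction (`wealth_from_income()`).

A *concentration table* (`build_concentration_table()`) lists, per rank of
each variable, the weighted frequency, the percentage, and the running
cumulative percentage. A *concentration curve* plots one cumulative
percentage against the other; the 45° diagonal (`equality_line()`) is the
locus of identical distribution. The scalar summaries are

* the concentration index \(C = 1 - 2\int_0^1 L(p)\,dp\), computed by the
  trapezoid rule — exact here, because the curve is piecewise linear by
  construction. \(C \in [-1, 1]\), \(C = 0\) on the diagonal, and \(C > 0\)
  when the curve lies **below** the diagonal. With exposure cumulated on
  the X axis and wealth on the Y axis, \(C > 0\) means the low-exposure end
  of the sample is poorer than average: exposure is concentrated among the
  wealthier categories.
* the maximum absolute deviation \(\max_p |L(p) - p|\) in percentage
  points, evaluated at the vertices (sufficient for a piecewise-linear
  curve, and invariant to inserting collinear points);
* a dominance class within a tolerance band: `on_equality`, `above`,
  `below`, or `crossing`;
* a percentile bootstrap interval for \(C\) (`bootstrap_index()`).

## Two curve constructions

The construction that pairs the two variables' *marginal* cumulative
distributions rank by rank — vertex \(i\) at
\((\mathrm{cum}\%X_i, \mathrm{cum}\%Y_i)\) — is the table-level recipe and
is provided as `mode = "paper"`. It reproduces the tabular presentation
exactly, but it is a function of the two marginals alone: it cannot detect
*association* between wealth and exposure. Two samples with identical
margins but opposite wealth gradients yield the same paper-mode curve.

`mode = "standard"` is the record-level construction used throughout
health-economics practice: records are ranked by the X variable in
ascending order, ties pooled within a rank, and \(L(p)\) is the cumulative
share of the Y variable's rank-weight score among the first \(p\)% of
X-ranked weight. Under independence \(L(p) \approx p\) regardless of the
margins, and a wealth gradient in exposure bends the curve off the
diagonal. Both modes are exposed; `standard` is the default for the index
and all inference, `paper` for reproducing the tabular/plotting
presentation. The axes follow the study convention (X = risk factor,
Y = wealth), the transpose of the conventional curve; passing
`x_variable = "wealth"` to `build_concentration_table()` gives the
conventional orientation, under which reversing the wealth-category order
negates the standard-mode index exactly (reversing the *ranked* variable is
an exact point reflection of the curve; reversing the *accumulated*
variable's scores instead rescales deviations by \(\bar s/(125-\bar s)\),
where \(\bar s\) is the mean score, and is exact only when \(\bar s = 62.5\)).

Zero-frequency ranks are kept in the table (frequency 0) and collapse to a
single curve vertex; Y mass that accumulates while X mass is still zero is
absorbed into the first positive-\(p\) segment so the curve always starts
at \((0,0)\) with strictly increasing \(p\).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_age` | 30 years | adult age floor applied before any analysis |
| `cum_weights` | 25/50/75/100 % | rank scores of the 4-category systems; a 5-category wealth option (`wealth_levels5()`) uses 20/…/100 |
| `tolerance` | 1 pp | dominance band half-width; 1 pp is the smallest gap visually resolvable on a standard-size curve figure |
| `boot_B` | 200 | bootstrap replicates for the 2.5/97.5 percentile interval |
| `mode` | `standard` | curve construction used for the index |

## The synthetic survey generator

Real DHS microdata are access-restricted, so `generate_survey()` emulates
the study population: by default n = 4,122 respondents aged uniformly on
30–90, equal quarters in the four wealth categories, unit weights, and one
4×4 row-stochastic matrix giving the exposure distribution conditional on
wealth. Every exposure column is drawn from the same matrix, so a
scenario's association structure is planted identically in each factor and
each built-in scenario is analysed on its namesake factor.

The five built-in scenario matrices are versioned constants encoding the
qualitative patterns the analysis is meant to distinguish, chosen a priori
from their expected rank scores (row · (25, 50, 75, 100)):

* `independent` — identical rows; expected score 47.5 in every category.
  The null against which calibration is checked.
* `alcohol` — a moderate gradient, expected scores 42.5 → 60 from poor to
  richest.
* `tobacco` — near-identical rows (max row-to-row total-variation distance
  0.02) around a low-use profile; expected scores 37.0–38.0, i.e. < 3%
  variation, and deliberately symmetric so the expected curve deviation is
  ≈ 0.
* `diet` — near-flat with a mild tilt: the lower-middle (`rich`) category
  most exposed (52.75), `richest` least (48.75); expected deviation ≈ 1 pp
  above the diagonal.
* `inactivity` — a strong gradient, 43.75 → 75; expected deviation ≈ 7 pp
  below the diagonal.

Ages are uniform because age enters the analysis only through the ≥ 30
filter; no household clustering, stratification or informative weighting is
emulated beyond a per-record weight column. Passing tests on these samples
therefore demonstrates correctness of the measurement chain and its
calibration under multinomial sampling — not robustness to the design
effects, interviewer effects or missing-data mechanisms of a real survey.

## Numerical and design choices

* **Probability validation** uses an absolute tolerance of 1e-9 on vector
  and row sums before any sampling happens.
* **Exposure draws** use one inverse-CDF comparison per record against the
  row of the wealth category, so a record set is a deterministic function
  of (config, seed); generators and the bootstrap save and restore the
  caller's RNG state.
* **Filtering order** is stated and audited: age floor first, then
  per-factor missingness, with counts (`input = output + removed_age +
  removed_missing`) carried into the pipeline manifest. A respondent
  missing one factor still enters the other factors' analyses, so
  per-factor n may differ.
* **Degenerate inputs**: an empty post-filter record set is a skip (with
  reason) in the pipeline and an error in direct table construction; a
  bootstrap replicate collapsing into one X category has the well-defined
  two-anchor curve and index 0.
* **Ties** within a rank are pooled; no within-rank ordering is invented.
* **Dominance at tolerance 0** classifies any nonzero deviation; the
  default 1 pp band absorbs sampling jitter at the study size.
* **Figures** are written as SVG and PNG (cairo). Vector text layout
  depends on the system font configuration, so byte identity of figures is
  not guaranteed across font environments; the plotted geometry in data
  units is deterministic, and the tests compare exactly that (polylines
  normalised by the reference diagonal).

## Problem sizes used in the test-suite

Distributional checks run at the sizes the analysis itself targets:
calibration of the independence null and gradient recovery at n = 4,122
over 50 seeds with B = 200 bootstrap replicates; scenario-shape checks at
n = 20,000; marginal-recovery goodness-of-fit at n = 20,000 over 100
seeds; curve axioms over 1,000 randomly generated tables.

## Limitations

* The paper-mode curve is descriptive only; any inferential statement
  (index sign, bootstrap interval) should use standard mode.
* The index is the plain (unnormalised) concentration index; Erreygers or
  Wagstaff corrections for bounded outcomes are out of scope, as are
  demographic standardisation and curve-crossing significance tests beyond
  the bootstrap interval.
* With only four ranks the curve has four informative vertices; the index
  resolution is correspondingly coarse, and small-sample indices are
  biased toward 0 by rank pooling.
* The package reports geometry — index, deviation, dominance — and
  attaches no causal interpretation to a curve's position.
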