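---
title: "Scoring a city against health-indicator standards: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring a city against health-indicator standards: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(benchtopsis)
```

## Why benchmark-anchored scoring

Composite sustainability indices usually compare cities with each
other: the alternatives in the TOPSIS decision matrix are cities, and
the ideal solutions are the best and worst observed performances.  That
construction answers "who is ahead?" but not "is anyone actually
meeting the standard?" — and it needs several comparable cities to work
at all.  `benchtopsis` implements the alternative construction in which
the ideal rows are *published health-indicator standards* (HIS): WHO
benchmarks, UN targets, national policy values.  Each indicator gets a
three-row decision column — the city's observed value, the positive
ideal `PI` (the standard to reach) and the negative ideal `NI` (the
floor to stay away from) — so a *single* city can be scored, and the
score is interpretable in absolute terms.

The hierarchy has three levels: dimensions (health, environment,
social, economic) contain elements (e.g. health status, air-pollution
management) which contain indicators (e.g. life expectancy, AQI).  The
bundled `khon_kaen_2019` fixture carries the full reference framework:
45 indicators in 15 elements and 4 dimensions, with the 2019
observation for Khon Kaen province, Thailand.

## Weighting: AHP with a consistency gate

Expert judgments arrive as Saaty pairwise-comparison matrices per
judgment group (one per element; dimensions whose elements hold a
single indicator each get one dimension-level group).  Entries lie in
$[1/9, 9]$ with $a_{ji} = 1/a_{ij}$ enforced to $10^{-9}$; validation
reports violations by label and never repairs them.

The priority vector uses the **normalised-PCM** method — divide each
column by its sum, average across rows.  The principal-eigenvector
method is available (`priority_vector(p, "eigen")`) as a cross-check;
the normalised-PCM form is the default because it is the construction
under which the bundled judgment tables reproduce cell by cell, and the
two agree exactly on consistent matrices.

Consistency is gated by $C.I. = (\lambda_{max} - n)/(n-1)$ and
$C.R. = C.I./R.I. < 0.1$, with $\lambda_{max}$ estimated as the mean of
$(Aw)_i / w_i$.  The random-index lookup ships in two variants:
`"printed"` (the table distributed with the reference framework, with
1.48 at $n = 12$) and `"saaty_classic"` (1.54 at $n = 12$); they agree
everywhere else.  For $n \le 2$ a reciprocal matrix cannot be
inconsistent, so $C.R.$ is defined as 0.  Any group at
$C.R. \ge 0.1$ aborts `weights_for_framework()` naming the group —
inconsistent judgments should go back to the experts, not into the
score.

### Weight precision

`weights_for_framework()` rounds exported weights to **two decimals by
default** (`digits = NULL` disables this).  Published AHP weight tables
are printed, cited and reused at two decimals, and the bundled worked
example is reproducible at printed precision exactly when the
two-decimal weights enter the weighting step.  All AHP-internal
quantities ($\lambda_{max}$, $C.I.$, $C.R.$) are always computed in
full precision, and everything downstream of the weights is full
precision until render time.

## Scoring: TOPSIS on a three-row panel

Per indicator $j$ with weight $w_j$, the column
$x = (\text{city}, PI, NI)$ is vector-normalised
($r = x/\lVert x\rVert_2$, so each component is in $[0,1]$ and any
common unit cancels — the score is invariant to rescaling a single
indicator's triple), weighted ($v = w_j r$), and the orientation-aware
extremes of $v$ over the three rows become $A^+$ and $A^-$.  Taking the
extremes over *all* rows (not just the benchmark rows) means a city
already beyond its standard defines its own ideal; the bundled
observation exercises this (ambulance provision exceeds the WHO
standard, household debt exceeds the tolerable ceiling).

Element and dimension scores pool the squared city-to-ideal deviations
of their member indicators:
$S^\pm = \sqrt{\sum_j (v_j - v_j^\pm)^2}$ and
$c^* = S^-/(S^+ + S^-) \in [0,1]$.  Dimension scores pool *raw
indicator* deviations — no second layer of element weights enters the
aggregation (verified against the reference results).  Ranks are
assigned by descending closeness within a peer group, ties broken by
ascending code, so output is deterministic.

```{r example}
fx <- bundled_fixture("khon_kaen_2019")
ev <- evaluate_city(fx$framework, fx$observation)
tidy(ev, "dimension")
```

### Degenerate inputs and numerical choices

* An all-zero column cannot be normalised and aborts with the
  indicator code.
* If the city coincides with both ideals, $S^+ + S^- = 0$; closeness is
  defined as 1 (the standard is met) with a warning.
* Printed-table views (`render_printed_tables()`) round half away from
  zero at the conventional precisions (2 decimals for ideals and
  closeness, 3 for deviations); rounding happens only at render time.
* Weights must lie in $(0, 1]$ and panel values must be non-negative;
  both are hard errors, not silent clamps.

## Unstated standards

Standards tables frequently print only one side of an indicator (a
target with no floor, or a ceiling with no target).  The framework
resolves the unstated side from an explicit per-indicator substitute
first, then from a framework-level default policy: `"zero"` (the
default — a natural floor for rates and percentages), `"one"`, or
`"omit"` (drop the indicator, with a warning).  Substitutes are stored
separately and never overwrite printed values; strategy classification
(below) uses printed standards only.  In the bundled fixture all
unstated cells resolve to zero except two mortality-rate floors (crude
deaths, diabetes deaths) that carry an explicit substitute positive
ideal of 1 per 100,000/1,000 — a zero mortality target is not a
meaningful floor for these, and the substitute of 1 is the value under
which the reference computation is reproduced.  Because the choice of
stand-in was reverse-engineered rather than documented at source, it is
recorded per indicator in the fixture file rather than hidden in code.

A note on fidelity: a handful of per-indicator cells and three element
rows of the published reference tables cannot be reproduced from the
published inputs under any uniform policy (they appear block-shifted or
transposed in typesetting), while all remaining element and dimension
rows reproduce exactly at printed precision.  The irreproducible cells
are excluded from the test suite's reproduction assertions and listed
there; one element separation sits on a rounding half-boundary and is
asserted to one unit in the last printed place.

## Strategy classification

Each indicator is placed into one of three levels against its *printed*
standards: Level 1 (growth-maintaining) at or beyond the positive
ideal, Level 2 (monitoring) between the standards, Level 3
(improvement) beyond the negative ideal; with a single printed
standard the rule is two-valued (good side → 1, bad side → 3).
Policy placements that a pure value rule cannot express ship as
explicit per-indicator overrides in the framework file, marked
`basis = "override"` in the output — the rule stays auditable and the
reference lists are reproduced exactly.

The IOC screening helper (`ioc_screen()`) computes the mean of expert
suitability ratings in $\{-1, 0, +1\}$ over an odd panel and retains
indicators at index $\ge 0.5$ (the conventional content-validity
threshold; configurable).

## Synthetic generator

`generate_framework()`, `generate_pcm()` and `generate_city()` emulate
the three evaluator inputs under a single seed with independent
sub-streams, so every pipeline stage is testable without real data:

* Frameworks draw orientations 50/50 and ideals with
  $0 < NI < PI$ (`MAX`) or $0 < PI < NI$ (`MIN`); missing ideals are
  injected only on the side whose natural substitute is the zero floor
  (NI for `MAX`, PI for `MIN`), the same missingness pattern real
  standards tables show.
* Judgment matrices start from perfectly consistent ratios
  $w_i/w_j$, perturb multiplicatively by $e^{\sigma z}$ and snap to the
  nearest admissible Saaty value, so generated matrices are always
  legal instruments; large $\sigma$ legitimately produces
  $C.R. \ge 0.1$ matrices (the generator reports the rate), which
  exercises the rejection path.
* City observations interpolate linearly between the resolved ideals:
  position 1 with zero jitter lands exactly on every positive ideal
  (closeness 1 everywhere), position 0 on every negative ideal
  (closeness 0), which is how the anchor properties are tested.

What the generator does **not** emulate: correlated indicators,
epidemiological time trends, measurement error structure, or spatial
effects.  Passing the property suite on synthetic data therefore shows
the *algebra* is right (anchors, bounds, scale invariance, oracle
equivalence), not that any particular real city's data are well
modelled.

## Problem sizes in the test suite

The reproduction tests run the full 45-indicator worked example (well
under a second).  The property suites use 100 seeded small synthetic
frameworks (2×2×2) for the anchor checks, 1,000 random three-row
panels against a brute-force oracle at $10^{-12}$, 25 random
consistent matrices ($n \le 9$) for exact weight recovery, and 100
seeds for the noise/rejection-rate check — sizes chosen to exercise
every branch while keeping the suite fast.

## Known limitations

* Closeness compresses all member indicators of an element into one
  number; two very different deficit patterns can score alike — read
  the per-indicator panels before acting on an element score.
* Standards change; scores are only as current as the framework's
  `PI`/`NI` values, and the package deliberately does not fetch them.
* The three-row construction makes each indicator's normalisation
  depend on the city's own value; cross-city comparisons should use
  one framework and per-city evaluations, not a pooled matrix (a
  multi-city pooled mode is intentionally out of scope).
* Group aggregation of multiple expert matrices (beyond one consensus
  matrix per group) and fuzzy/entropy weighting variants are out of
  scope.
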