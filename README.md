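# benchtopsis

Benchmark-anchored TOPSIS with AHP weights for single-city
health-sustainability assessment.

## The problem

Most composite sustainability indices rank cities against *each other*,
which tells a policymaker little: the "most sustainable" city in a
league table may still miss every health target, and a city with no
peers in its context cannot be ranked at all.  `benchtopsis` instead
scores one city against *published health-indicator standards* (HIS) —
WHO benchmarks, UN targets, ministry policy values — organised in a
hierarchical framework of dimensions (health, environment, social,
economic), elements (e.g. health status, air pollution management), and
indicators (e.g. life expectancy, AQI).  The output says, per
indicator, element and dimension, how close the city is to the standard
it should meet, and which improvement strategy applies.

## The method

**Weighting (AHP).**  For each judgment group a Saaty pairwise
comparison matrix \(A = (a_{ij})\), \(a_{ij} \in [1/9, 9]\),
\(a_{ji} = 1/a_{ij}\), is reduced to a priority vector by
column-normalisation and row-averaging (the normalised-PCM method).
Consistency is gated by

\[
C.I. = \frac{\lambda_{max} - n}{n - 1}, \qquad
C.R. = \frac{C.I.}{R.I.} < 0.1,
\]

with \(\lambda_{max}\) the mean of \((Aw)_i / w_i\) and \(R.I.\) the
size-dependent random index.  Any group failing the test aborts the
evaluation.

**Scoring (benchmark-anchored TOPSIS).**  Each indicator forms a
three-row decision column \(x = (\text{city}, PI, NI)\): the observed
value plus the positive- and negative-ideal standards.  The column is
vector-normalised \(r = x / \lVert x \rVert_2\), weighted
\(v = w_j r\), and the orientation-aware extremes of \(v\) over the
three rows become \(A^+\) and \(A^-\) — so a city already beyond its
standard defines its own ideal.  Squared city-to-ideal deviations are
pooled over each element and dimension:

\[
S^+ = \sqrt{\sum_j (v_j - v_j^+)^2}, \quad
S^- = \sqrt{\sum_j (v_j - v_j^-)^2}, \quad
c^* = \frac{S^-}{S^+ + S^-} \in [0, 1],
\]

with \(c^* = 1\) meaning the city sits on its standards and
\(c^* = 0\) on the negative ideals.  A three-level strategy classifier
(growth-maintaining / monitoring / improvement) then places every
indicator relative to its printed standards.

## Worked example

The bundled fixture is a 45-indicator, 15-element, four-dimension
framework with its expert judgment matrices and the Khon Kaen (Thailand)
2019 observation:

```r
library(benchtopsis)

fx  <- bundled_fixture("khon_kaen_2019")
w   <- weights_for_framework(fx$framework)   # AHP weights, C.R.-gated
ev  <- evaluate_city(fx$framework, fx$observation, w)
ev
#> <city_eval> Khon Kaen (2019) against framework 'khon_kaen_2019'
#>   45 indicators, 15 elements, 4 dimensions
#>
#> Dimension closeness:
#>  dimension s_plus s_minus closeness rank
#>       HEDm  0.409   0.430     0.513    3
#>       ENDm  0.366   0.144     0.282    4
#>       SODm  0.422   0.517     0.550    2
#>       ECDm  0.230   0.305     0.570    1
```

The economy dimension is closest to its standards (c\* = 0.57, rank 1)
and the environment furthest (c\* = 0.28, rank 4).  Element detail and
strategy levels:

```r
tidy(ev)                                  # element closeness with ranks
tidy(ev, "indicator")                     # per-indicator panels
classify_strategy(fx$framework, fx$observation)
autoplot(ev)                              # closeness bars by dimension
```

For example the household-debt element scores c\* = 0.00 (the city
exceeds the tolerable debt ceiling, Level 3 improvement), while
ambulances per population are above the WHO standard (Level 1
growth-maintaining).

A command-line wrapper ships in `inst/exec/benchtopsis`
(`evaluate`, `weights`, `screen`, `strategy`, `synth`, `fixtures`
subcommands), and `generate_framework()` / `generate_city()` produce
seeded synthetic inputs for testing pipelines without real data.

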