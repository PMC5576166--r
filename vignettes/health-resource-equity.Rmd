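---
title: "Measuring geographic equity of health care resources"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring geographic equity of health care resources}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hequity)
```

## The problem

A country's health workforce can be fairly shared among its *people* while
being extremely concentrated in *space*. Mongolia in 2014 is the canonical
example this package is built around: about three million people, over half
of them in or near the capital, spread over 1.56 million km² at fewer than
two persons per km². `hequity` takes a region-level table of raw counts —
population, land area, physicians, nurses, hospital beds — and quantifies
distributional equity on both weight bases: per 10 000 population and per
1 000 km² of area.

Raw counts are the only stored inputs. Published versions of such tables
often carry derived density columns, and in the Mongolian table a handful of
those cells (several per-10 000 physician values, and the demographic-density
cells of the capital and of Orkhon) are inconsistent with the raw
population, area and count printed in the same row, while the raw values
are self-consistent (they reproduce the row totals and the per-area
column exactly). The package therefore treats raw counts as authoritative
and always recomputes densities at full precision, rounding half-up to one
decimal only at report time.

## Lorenz curves and the Gini coefficient for grouped data

For regions $l = 1,\dots,S$ with weight $f_l$ (persons on the population
basis, km² on the area basis) and density $x_l$ (resource per weight unit),
regions are sorted by ascending $x_l$ (ties broken by region name — the
coefficient is provably invariant to the tie order, and a test asserts it)
and the Lorenz curve is the polyline through

$$(p_k, q_k) = \Big(\tfrac{\sum_{l \le k} f_l}{\sum_l f_l},\;
\tfrac{\sum_{l \le k} f_l x_l}{\sum_l f_l x_l}\Big), \qquad k = 0,\dots,S.$$

Two estimators of the concentration coefficient are provided:

* **Trapezoid** (the default): $G = 1 - \sum_k (p_k - p_{k-1})(q_k +
  q_{k-1})$, i.e. twice the area between the curve and the diagonal. It is
  basis-agnostic — fractional weights such as km² need no integerization.
* **Grouped formula**: $R = \sum_l (i_{l-1} + i_l - 1) f_l x_l / ((n-1)
  A_n) - 1$ with $i_l$ the cumulative weight, $n$ the total weight and
  $A_n = \sum_l f_l x_l$. We read $i_l$ as the cumulative count of atomic
  units (each region being $f_l$ identical units holding $x_l$ each) —
  the only reading under which perfect equality yields exactly 0 and
  perfect concentration exactly 1; the reading extends continuously to
  real-valued weights.

The only difference between the two is the $n-1$ versus $n$ denominator, so
they agree to within $1/n$; with population weights in the millions they
agree to five or more decimals, and the package tests both routes against a
third: a brute-force mean-absolute-difference oracle
$\sum_{ij} |y_i - y_j| / (2 n^2 \bar y)$ evaluated by literal double loop
over expanded atomic units (refused above $10^4$ units).

On the fixture the coefficients are 0.18/0.07/0.07 (physicians, nurses,
beds per population) and 0.74/0.68/0.69 (per area). Two of these are
sometimes quoted as 0.06 and 0.67; the raw-count computation gives 0.0689
and 0.6798, within 0.01 of those figures before rounding — the input
table's own rounding is enough to account for the difference, and we make
no attempt to tune toward either quotation.

## Settlement classification and group comparison

Regions are classed by demographic density: urban above 200 persons/km²,
suburban above 10, rural otherwise. The thresholds are read strictly
("higher than"), so a density of exactly 10 or 200 falls to the lower
class. On the fixture this yields 1 urban, 2 suburban and 19 rural regions.
Per-category summaries are **unweighted** means of the per-region
indicators — not pooled ratios — because that is what the reference
summaries of the fixture contain (the rural per-area physician mean of 2.7
equals the unweighted mean, not the pooled ratio).

The urban+suburban pool is compared with the rural pool by the
Mann–Whitney U test, computed from midranks. Two methods are exposed:

* **Exact**: full enumeration of the $\binom{n_1+n_2}{n_1}$ label
  assignments of the observed pooled multiset (ties handled naturally),
  refused above $10^6$ assignments; two-sided p doubles the smaller tail,
  capped at 1.
* **Asymptotic** (default): normal approximation with tie-corrected
  variance and a continuity correction of 1/2.

The asymptotic continuity-corrected variant is the default because it is
what mainstream software reports for small grouped comparisons and it
reproduces the reference results for this fixture: p = 0.045 for physicians
per population, and p = 0.0074 for all three resources per area, where the
3-vs-19 split is completely separated (U = 57 = n₁n₂, every urban/suburban
region denser than every rural one — which is also why all three area-basis
tests share a single p). Exact enumeration under complete separation would
instead give $2/\binom{22}{3} \approx 0.0013$; the exact method remains the
statistically preferable choice for small tie-free data and is available via
`method = "exact"`.

## Supply categories

Map-style supply classes are derived by Fisher–Jenks natural breaks: the
exact dynamic program minimizing total within-class sum of squares over
contiguous partitions of the sorted densities. It is deterministic — no
seeds, unlike k-means — and standard for choropleth classing. The default
is k = 4 classes labelled red < orange < yellow < green (red = inadequate,
green = adequate); breakpoints sit at midpoints between adjacent classes,
and a value exactly on a breakpoint joins the higher class. One override
applies on the area basis only: any density of at most 1 resource per
1 000 km² is forced red, the conventional inadequate-supply rule. The
override cannot break monotonicity of the assignment (values ≤ 1 are below
any sensible break; if clustering did place a break below 1 the override
simply restores order, which a property test asserts). The reference
analysis states neither its clustering algorithm nor its cut-off values, so
this module is validated structurally — against exhaustive partition search
for n ≤ 15 — rather than against printed breakpoints.

## The synthetic generator

`generate_table()` emulates the *shape* of the fixture rather than its
values: a small number of exchangeable regions, heavy-tailed sizes, and
region-level densities of controllable inequality.

* Region shares of total population and total area are symmetric
  Dirichlet; the default concentration of 0.5 produces the
  one-dominant-region profile typical of capital-centred countries.
  Totals default to Mongolia's scale (3 × 10⁶ persons, 1.5 × 10⁶ km²).
* Per-region densities are log-normal(μ, σ) per 10 000 persons; defaults
  μ = log 25, σ = 0.3 give physician-like levels and a closed-form
  equal-weight Gini of $2\Phi(\sigma/\sqrt2) - 1 \approx 0.17$, close to
  the fixture's population-basis coefficients.
* Counts are `round(density × population / 10 000)`, so at σ = 0 the Gini
  is only rounding-close to zero (≤ 0.01 with region populations of 10⁵),
  and exact ties across regions occur only for zero-count resources; the
  tests state those tolerances rather than hiding them.
* Each table draws from a stream seeded by its spec; the caller's RNG
  state is saved and restored, so generation never perturbs global
  randomness and identical specs give identical tables.

`generate_separated_groups()` designates the first `n_urban` regions as an
urban subset (densities multiplied by a shift factor, areas shrunk so
demographic density exceeds 200/km², remaining regions pinned rural so the
designed split is exactly the settlement split). With shift ≥ 10 it
reproduces complete separation; with shift = 1 the groups are exchangeable,
giving a clean type-I-error harness for the settlement comparison. Note
that with a 3-vs-19 split the U distribution is discrete: the true
rejection rate of the nominal 0.05 test is about 0.04, which is what the
calibration test expects to see.

What passing these checks does **not** show: real administrative data have
spatial autocorrelation, within-region heterogeneity (district-level
clustering of staff inside a province), and correlated resource types; the
generator's regions are exchangeable and its resources independent. The
validation demonstrates estimator correctness, not realism of any
particular country's geography.

## Numerical conventions

* Densities and coefficients keep full double precision internally;
  reporting uses round-half-up (1 decimal for densities, 2 for Ginis, the
  conventions of the reference tables). `round_half_up()` is exported.
* Lorenz endpoints are pinned to exactly (0,0) and (1,1) against
  floating-point drift of the final cumulative sum.
* WHO thresholds (22.8 minimum, 44.5 SDG-era) are inclusive at the named
  value and applied to physicians + nurses per 10 000, the table carrying
  no midwife category.
* Degenerate inputs fail loudly and early: all-zero resources refuse a
  Lorenz curve ("degenerate"), `k` above the number of distinct values
  refuses natural breaks, an empty settlement pool refuses the comparison,
  and the report tags every propagated error with its pipeline stage.

## Problem sizes

All reference computations are desk-scale (22 regions). The validation
suite uses 5–15-region instances for the brute-force oracles, 100–200
equal-weight regions for closed-form Gini recovery, and 200 seeds for the
type-I-error calibration; the complete test suite runs in well under a
minute on one CPU.

## Limitations

* No confidence intervals or bootstrap for the Gini point estimates, and
  no within/between decomposition.
* No multiple-testing adjustment across the six comparisons (none is
  applied in the reference analysis being reproduced).
* No cartography: supply categories are emitted as tables keyed by region
  name, ready to join to any mapping layer, but the package draws no maps.
* The settlement thresholds (10 and 200 persons/km²) are a convention for
  countries without an official urban/rural demarcation, not a universal
  standard.
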