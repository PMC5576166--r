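# hequity

Geographic equity analysis of health care resources across a country's
administrative regions.

Health planners routinely ask two different fairness questions about the same
workforce table. *Does supply match people?* — resources per 10 000
population. *Does supply match geography?* — resources per 1 000 km² of land.
In a sparsely settled country the answers can diverge spectacularly: a
per-capita-equitable system can still leave herders hundreds of kilometres
from the nearest physician. `hequity` quantifies both views from nothing more
than a region-level table of raw counts (population, land area, physicians,
nurses, hospital beds), and ships the 2014 Mongolian province table as a
fully worked fixture.

## What it computes

For a table of regions *l = 1..S* with weights *f\_l* (persons or km²) and
resource densities *x\_l*, the package builds the **Lorenz curve** — regions
sorted by ascending density, point *k* at (cumulative weight share,
cumulative resource share) — and the **Gini concentration coefficient**, both
as the trapezoidal integral

> G = 1 − Σₖ (pₖ − pₖ₋₁)(qₖ + qₖ₋₁)

and via the classical grouped concentration-ratio formula

> R = Σₗ (iₗ₋₁ + iₗ − 1) fₗ xₗ / ((n − 1) Aₙ) − 1

with *iₗ* the cumulative weight, *n* the total weight and *Aₙ* = Σ fₗxₗ. The
two differ only through the (n − 1) vs. n denominator and agree to within
1/n; a brute-force mean-absolute-difference oracle provides a third,
independent route for validation.

Around that core:

- **Settlement classification** — urban (> 200 persons/km²), suburban
  (> 10), rural (otherwise) — with unweighted per-category mean densities.
- **Mann–Whitney U comparison** of urban+suburban vs. rural indicator
  values: exact enumeration of the permutation distribution (tie-aware) or
  the tie-corrected normal approximation with continuity correction.
- **Fisher–Jenks natural breaks** (exact 1-D dynamic program) deriving
  red/orange/yellow/green supply categories for choropleth-style reporting,
  with the inadequate-supply rule that any area-basis density ≤ 1 per
  1 000 km² is red.
- **WHO workforce thresholds** (22.8 and 44.5 physicians + nurses per
  10 000).
- A **synthetic region-table generator** (Dirichlet sizes, log-normal
  densities) whose population-basis Gini tracks the closed form
  2Φ(σ/√2) − 1, used to validate every stage without external data.

## Worked example

```r
library(hequity)

mn <- load_mongolia_2014()
gini_table(mn)
#>   resource      basis        gini gini_rounded
#> 1 physicians    population 0.184          0.18
#> 2 nurses        population 0.0707         0.07
#> 3 hospital_beds population 0.0689         0.07
#> 4 physicians    area       0.745          0.74
#> 5 nurses        area       0.680          0.68
#> 6 hospital_beds area       0.689          0.69

utest_table(mn)
#>   resource      basis          U    n1    n2 p_two_sided stars
#> 1 physicians    population    50     3    19     0.0445  "*"
#> 2 nurses        population    45     3    19     0.126   ""
#> 3 hospital_beds population    41     3    19     0.251   ""
#> 4 physicians    area          57     3    19     0.00739 "**"
#> 5 nurses        area          57     3    19     0.00739 "**"
#> 6 hospital_beds area          57     3    19     0.00739 "**"
```

Read: per 10 000 population the three resources are near-equally distributed
(Gini 0.07–0.18) and only physicians differ significantly between the
urban+suburban and rural pools (p = 0.04). Per 1 000 km² the picture flips —
Ginis of 0.68–0.74 and complete urban/rural separation (U = 57 of 57
possible pairs, p = 0.007 for all three resources). The full pipeline,
including Lorenz points, supply categories and WHO assessment, is one call:

```r
rep <- run_full_analysis(mn)
write_report(rep, "mongolia-report")      # CSVs + provenance.json
plot_lorenz(mn, "area")                   # ggplot, curves far from diagonal
plot_density_scatter(mn, "physicians")    # log-log scatter, capital top-right
```

A command-line front end with the same verbs lives at
`inst/scripts/hequity-cli.R`:

```sh
Rscript inst/scripts/hequity-cli.R analyze --output-dir report/
Rscript inst/scripts/hequity-cli.R compare --resource physicians --basis area
```

## Methods notes

See `vignettes/health-resource-equity.Rmd` for the model, the estimator
conventions (denominators, tie handling, rounding), the synthetic
generator's assumptions, and known limitations — including the few cells of
the source table whose printed derived densities are inconsistent with their
own raw counts, and why raw counts are treated as authoritative.
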