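---
title: "Methods: demand, potential, allocation and validation in luccr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: demand, potential, allocation and validation in luccr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(luccr)
```

`luccr` simulates land-use and cover change (LUCC) on a regular cellular
grid by coupling three components — exogenous national demand, a per-cell
change potential from spatial regression, and an iterative competitive
allocation — and validates the result against observed maps at multiple
resolutions. This vignette documents the model as implemented: its
assumptions, the tunable parameters, the numerical choices, and what the
synthetic test systems do and do not establish about behaviour on real
data.

## The cellular space

A `lucc_grid` holds, per cell, the percentage of the cell's area under six
dynamic classes (forest vegetation, grassland vegetation, planted pasture,
agriculture, mosaic of occupation, forestry) and a static *others* class
(urban areas, water, bare land), which never changes during a run. Valid
cells satisfy two invariants that every operation preserves: each fraction
lies in [0, 100], and the fractions including *others* sum to 100 within
10⁻⁶. Cells outside the study region (`valid = FALSE`) are excluded from
neighbourhoods, regressions and area accounting, accommodating irregular
national boundaries on the rectangular lattice.

The default cell side is 10 km (`cell_side_km = 10`), so a cell is 100 km²
and national class areas in km² are `sum(percent)/100 × 100`. Distances
are centroid-to-centroid Euclidean in projected km; on-disk projection
metadata is a free-text tag (default `"EPSG:5880"`) — the package performs
no reprojection, because the synthetic lattice is abstract.

Neighbourhood structure is first-order contiguity, **queen** by default
(rook available), row-standardised. Queen contiguity is the standard
choice for lattice spatial-lag models and matches the intuition that a
cell's land use responds to all adjacent cells; descriptions of this model
family state only that neighbourhood influence is considered, so the
scheme is exposed as a parameter with a documented default rather than
hard-wired. The adjacency is symmetric, has no self-neighbours, and
isolated cells keep empty weight rows.

Two raster-to-cell integration operators mirror common cell-filling
practice: `aggregate_percentage()` (share of true pixels per cell block)
and `aggregate_min_distance()` (minimum Euclidean distance from the cell
centroid to any true pixel centroid, zero if the cell contains one; an
empty mask returns a configurable sentinel, default 10⁶ km, with a
warning).

## Demand

Demand is precomputed and linear: for class *c* with endpoint areas
$L_c(t_i)$ and $L_c(t_f)$,

$$C_{ca} = \frac{L_c(t_f) - L_c(t_i)}{n_t}, \qquad
  D_c(t_k) = D_c(t_{k-1}) + C_{ca},$$

with $n_t = t_f - t_i$ years and $D_c(t_i) = L_c(t_i)$. The
implementation iterates the recursion rather than evaluating the closed
form so that the stored series is exactly the one the allocation consumes;
tests verify the recursion closes on the printed endpoints to within
10⁻⁶ km² and agrees with the closed form to machine precision.

Endpoint tables for the three built-in scenarios (`scenario_endpoints()`)
are in km² for 2000–2050. Their national dynamic totals agree across
scenarios to within 1 km² (printed-table rounding), which matters because
allocation conserves total dynamic area exactly: `allocate_year()` refuses
demand whose total drifts from the current landscape total by more than
the allocation tolerance. Per-year demand overrides are possible by
editing the series before a run; the default is strictly linear.

## Potential

### Driver screening and model selection

Candidate driver fields are screened pairwise by Spearman correlation:
no retained pair may exceed |ρ_S| = 0.60. Only the threshold is a protocol
constant; the pruning order is this package's choice and is deterministic — offending pairs are visited in
descending |ρ_S| and the member with the larger mean absolute correlation
to the remaining candidates is dropped (ties resolve toward the driver
more correlated with the response, then toward earlier listing). Constant
fields correlate as 0, with a warning.

`select_model()` fits one spatial-lag model per candidate driver set and
returns the minimum-AIC model among those whose driver coefficients all
have p < 0.05. The pseudo-R² reference level (0.75) is recorded as a flag
rather than enforced, because in the protocol this mirrors it is an
across-class average criterion, not a per-model gate. If no specification
passes the significance filter, the overall minimum-AIC model is returned
flagged non-compliant, with a warning — a deliberate fallback so that
pipelines degrade loudly instead of failing.

### The spatial-lag estimator

The potential model for class *c* is the simultaneous-autoregressive lag
model on the class fraction $y \in [0,1]$:

$$y = \rho W y + X\beta + \varepsilon, \qquad
  \varepsilon \sim N(0, \sigma^2 I).$$

Estimation is by maximum likelihood with the likelihood concentrated in ρ:
for fixed ρ, β(ρ) and σ²(ρ) are closed-form least-squares quantities, and
the profile log-likelihood

$$\ell(\rho) = -\tfrac{n}{2}\left(\log 2\pi\sigma^2(\rho) + 1\right)
  + \log\lvert I - \rho W\rvert$$

is maximised by one-dimensional search (`stats::optimize`, tolerance
10⁻⁸) over the admissible interval $(1/\lambda_{\min}, 1/\lambda_{\max})$
given by the extreme eigenvalues of W. The log-determinant is evaluated
*exactly* from the eigenvalues of the symmetric similar matrix
$D^{-1/2} A D^{-1/2}$, computed once per weights object and cached; at the
package's desk scales (lattices up to ~50 × 50 cells in routine use) this
is fast and makes fits reproducible to machine precision. Tests compare
the reported log-likelihood against a dense brute-force evaluation
(explicit determinant over a ρ grid) to 10⁻⁶.

Standard errors come from the inverse numerical Hessian of the full
log-likelihood at the optimum (in (β, ρ, log σ²) coordinates); p-values
are Wald. The pseudo-R² is the squared correlation between the observed
and predicted response — the "determination coefficient" of a spatial-lag
fit is not uniquely defined, and this choice is simple, bounded and
monotone in fit quality. AIC is $2k - 2\ell$ with $k$ = number of
estimated parameters (β, σ², and ρ when free). Fixing `rho = 0` reduces
the fit to OLS exactly, which the tests exploit as a nesting check.

### From regression to potential

The potential of class *c* in cell *xy* at year *t* is the prediction
minus the previous year's fraction, clamped:

$$\mathrm{Pot}_{cxyt} = \mathrm{clamp}\!\left(
  \rho\,(W y_{t-1})_{xy} + X_{xy}\beta - y_{t-1,xy},\ -1,\ 1\right).$$

Prediction uses the *conditional* form ρ·W·y_observed(t−1) + Xβ, not the
reduced form $(I-\rho W)^{-1}X\beta$: the potential is defined against the
previous year's map, and the conditional form keeps yearly updates local
and cheap. Because y is a fraction in [0, 1], the [−1, 1] clamp is the
natural range. Potentials are recomputed from the current map every
simulated year, so they are dynamic: as a class grows, its own and its
neighbours' fractions feed back through the ρW term.

Calibration is on *levels* at the calibration year (fit the fraction map
on drivers), with forward behaviour checked on simulated change; and the synthetic recovery
experiments use the exact SAR data-generating process, where levels
estimation is the correct likelihood.

### Restrictions

Scenario premises enter as data, not code: a mask schedule of entries
`(year_from, mask, class_group, protection_level)`. For a restricted
class (by default the four anthropic classes) in a masked cell, positive
potential is multiplied by `1 − protection_level × mask`; negative
potential (contraction/regeneration) is never restricted. Because the
active entry is the latest `year_from ≤ year`, premises like "protection
weakens from 2030" are one schedule row. Restrictive variables can also
enter as ordinary regression covariates; both pathways coexist.

## Allocation

Each simulated year distributes the demanded change
$D_c - A_c$ (target minus current national area) across cells:

1. **Candidate deltas.** $\delta_{c,xy} = E_{c,xy} \cdot \mathrm{ITF}_c$,
   where the *effective potential* $E$ is the model potential plus an
   adaptive demand-pressure offset (below), sign-gated so a class only
   changes in cells whose effective potential sign matches its national
   demand direction.
2. **Competition.** Within each cell, requested gains and losses are
   clipped to the feasible range ([0, 100 − others] per class) and the
   oversubscribed side is scaled down proportionally to its requested
   magnitudes, so deltas sum to zero per cell and the composition stays
   valid. Proportional scaling is deterministic and order-independent;
   with continuous fractions no tie-breaking is required. An infeasible
   request (gains with no colocated losses, or vice versa) resolves to
   zero change in that cell.
3. **Factor update.** $\mathrm{ITF}_c \leftarrow \mathrm{ITF}_c\,
   (1 + \lambda\, d_c (D_c - A_c)/\max(|D_c - A_c^{(0)}|, \text{floor}))$,
   with $d_c$ the demand direction, gain λ = 0.5, the update factor
   clamped to [0.5, 2] and the factor itself to [10⁻⁹, 10⁹]. Normalising
   by the demanded *yearly change* (not the demand total) keeps the
   update responsive; the direction term makes the factor grow whenever
   the class is short of its target regardless of the change's sign.

Iteration stops when every class's $|A_c - D_c|$ is within
`max_error × total study area` (default 0.5%), or at `max_iterations`
(default 1000), in which case a convergence error carrying the report is
raised (or a warning, if configured).

**Why the demand-pressure offset exists.** Descriptions of the allocation
factor in this model family are verbal; a purely multiplicative factor
with sign gating is the most literal reading, and `pressure_step = 0`
restores exactly that mechanism. But a multiplier can only rescale change
within cells whose potential sign already agrees with the demand
direction. In multi-decade runs with sustained growth, a class eventually
exceeds its regression-predicted level in every cell — its
positive-potential frontier empties — and no finite multiplier can
allocate further growth; the same happens to sustained contraction. The
offset is the classic cure from the CLUE lineage (an additive iteration
variable on the propensity): when a class's gap stops shrinking while its
demand is unmet, its effective potential is shifted by `pressure_step`
(default 0.02, potential units) per stalled iteration in the demand
direction, which recruits additional cells *in order of their potential*.
The mechanism is inactive whenever the multiplicative factor suffices, so
it changes nothing in the easy years and makes long scenario runs
feasible in the hard ones. With the offset disabled, a demanded expansion
of a class whose potential is non-positive everywhere correctly ends in a
convergence error.

Conservation is structural: *others* is copied bit-for-bit, competition
zeroes each cell's net dynamic change, and therefore national dynamic
area is constant over the run.

No explicit transition matrix restricts which classes may exchange;
legal-reserve-style rules can be approximated by restriction masks or
per-cell caps encoded in the *others* fraction.

## Scenario engine

`run_scenario()` advances year by year: scheduled driver updates →
potential recomputation per class → restriction damping → allocation. All
scenario differences (endpoints, mask schedule, driver schedule) are
data in the `scenario_config`; the engine is scenario-agnostic and fully
deterministic given its inputs — the recorded seed matters only for
generating synthetic inputs. Snapshots are kept for configurable years
(default: all), and every run records a canonical-JSON config hash that is
stable under key reordering.

## Validation

For one class, with observed maps at $t_0$ and $t_f$ and a simulated map
at $t_f$, change fields are $\Delta\mathrm{real} = \mathrm{real}_{t_f} -
\mathrm{real}_{t_0}$ and $\Delta\mathrm{sim} = \mathrm{sim}_{t_f} -
\mathrm{real}_{t_0}$. At window size *w* the grid is partitioned into
$w \times w$ blocks — partial blocks at the edges are kept, so no cell is
discarded — and

$$NS_w = \left(1 - \frac{\sum_j \lvert \Delta\mathrm{sim}_j -
  \Delta\mathrm{real}_j\rvert}{2 \sum_j \lvert \Delta\mathrm{real}_j
  \rvert}\right) \times 100 .$$

The implementation follows the Costanza-style multi-resolution fit, and
reports both the
raw value and the [0, 100]-clamped value. When observed change is zero
everywhere, NS is 100 if simulated change is also zero and 0 otherwise
(the limiting behaviour; avoids 0/0). Window 1 is the per-cell fit;
growing windows degrade resolution and separate location error from
pattern error.

The error decomposition reports, per class: `fit_patterns` (map-level
agreement of the final maps, $(1 - \sum\lvert \mathrm{sim} -
\mathrm{real}\rvert / 2\sum \mathrm{real}) \times 100$),
`fit_modified_areas` (the same statistic restricted to cells whose
observed change exceeds `change_threshold`, default 0; undefined → NA
with a warning when no cell qualifies), and omission/commission errors
(positive parts of $\lvert\Delta\mathrm{real}\rvert -
\lvert\Delta\mathrm{sim}\rvert$ and its reverse, as a percentage of total
valid area). Validation runs on fractional fields per class — maps are
never hardened to a single dominant class.

A "patterns" accuracy figure can mean either NS at a specific window or
the all-cell statistic; both are reported so either reading is
available. National-scale accuracy values require real observed national
maps and a real driver database and are out of scope here; the test suite replaces them with the
estimator-recovery, oracle-equivalence, conservation and metric-property
checks described below.

## The synthetic study system

`synthetic_spec()`/`gen_landscape()` generate complete landscapes:

- **Drivers**, one per driver category of interest: a smooth
  *suitability* field (SAR-smoothed noise, ρ = 0.85, standardised), a
  *distance-to-features* field (minimum distance to randomly placed
  infrastructure cells, standardised), and a deterministic north–south
  gradient (*grad_ns*) standing in for broad agrarian-structure
  contrasts. A *protected* mask is the upper tail (default 15%) of an
  independent smooth field — contiguous blobs, like real protected-area
  networks.
- **Class fractions**: one latent score per class from the exact SAR
  process $z_c = (I - \rho W)^{-1}(X\beta_c + \varepsilon_c)$ with known
  (ρ, β, σ), standardised and passed through a temperature-controlled
  softmax onto $100 - \text{others}$. The softmax guarantees the
  compositional invariants for any latent values while preserving each
  driver's monotone effect; *others* defaults to 7% everywhere.
  Defaults: 50 × 50 cells, ρ = 0.5, σ = 0.1, temperature 0.75, and a
  fixed 6 × 3 loading matrix that separates the classes along the three
  drivers. These were chosen once to give heterogeneous, strongly
  autocorrelated maps with every class present in most cells — the
  regime in which fractional allocation with competition is meaningful.
- **Scenario-shaped demands**: `synthetic_endpoints()` takes a built-in
  scenario's *annual* national changes, rescales them to the synthetic
  study area and horizon, re-centres them to conserve total dynamic area
  exactly, and anchors them at the landscape's actual class totals — so
  the direction-of-change pattern matches the scenario and the demand is
  exactly conservative.
- **Observed pairs**: `gen_observed_pair()` produces $(t_0, t_f)$ by
  calibrating potential models on $t_0$ (mirroring the real workflow of
  calibrating on an observed base year) and running the engine forward;
  the pair carries ground truth for bookkeeping and validation tests.

Note an important asymmetry: the *latent* scores are exactly SAR, but the
softmax makes the *fractions* a nonlinear transformation of them, so a
spatial-lag fit on a landscape fraction estimates the autocorrelation of
the transformed field (typically higher than the latent ρ), not the latent
ρ itself. Estimator-recovery claims are therefore tested on the direct
SAR process via `gen_sar_field()` — where the likelihood is correctly
specified — at the documented conditions (50 × 50 lattice, ρ = 0.5,
β = (1, 2), σ = 0.1, 20 replicates).

What passing synthetic tests do **not** show about real data: real driver
fields are not standardised Gaussians, real class maps have hard zeros
and biome structure the softmax never produces, real calibration pairs
embed measurement error and class-definition changes, and real demand is
not exactly linear. The synthetic system establishes internal
correctness — estimator consistency, conservation, convergence, metric
identities — not predictive skill.

## Problem sizes and runtimes in the test suite

Routine tests use lattices between 3 × 3 and 20 × 20; the
estimator-recovery and long-run checks use the default 50 × 50 lattice
(2,500 cells), 20 regression replicates, and one 50-year scenario-shaped
run. These sizes were chosen as the smallest at which the statistical
claims are stable (spatial-lag estimation is noticeably biased on very
small lattices) while keeping the whole suite in the tens of seconds on
one core.

## Known limitations

- One potential model per class for the whole region; per-biome models
  can be emulated by fitting on subsets but there is no built-in region
  switch in the engine.
- The allocation is heuristic: convergence to within tolerance is
  enforced, optimality of the spatial pattern is not defined, and
  results depend (deterministically) on the gain and pressure settings.
- Spatial-error and SARAR specifications, heteroscedasticity-robust
  inference, and geodesic distances are not implemented.
- NetCDF serialisation is not provided; cell-table CSVs with metadata
  headers are the interchange format, and their round trip preserves
  fractions to 10⁻⁶.
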