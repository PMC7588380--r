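---
title: "Methods: PM2.5-attributable mortality under WHO guideline scenarios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PM2.5-attributable mortality under WHO guideline scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmburden)
```

## The problem

Ambient fine particulate matter (PM2.5) is a leading mortality risk factor.
Comparative risk assessment (CRA) asks: how many deaths in a population
would not have occurred if exposure had been at some counterfactual level?
`pmburden` implements the full CRA chain for ambient PM2.5 and, on top of
it, a *scenario analysis*: how much of the attributable burden would
disappear if grid-cell exposures were capped at the WHO interim targets
(IT1 = 35, IT2 = 25, IT3 = 15 µg/m³) or the air quality guideline level
(AQG = 10 µg/m³ annual mean).

The chain combines three inputs per country:

1. a **gridded exposure surface** — cells with an annual-mean PM2.5
   concentration and a resident population;
2. **baseline mortality** — deaths by cause, sex and age group for the five
   causes with established PM2.5 associations: ischaemic heart disease
   (IHD), stroke, COPD and lung cancer (adults over 25) and acute lower
   respiratory infection (LRI, all ages);
3. **exposure–response curves** — parameter draws of a nonlinear
   relative-risk function per cause (and per age band for the
   cardiovascular causes).

## The model

### Relative risk

The default curve family is the integrated exposure–response (IER) form,

$$RR(z) = 1 + \alpha\left(1 - e^{-\gamma (z - z_{cf})^{\delta}}\right),
  \qquad z > z_{cf},$$

and $RR(z) = 1$ for $z \le z_{cf}$. $\alpha \ge 0$ sets the asymptotic
excess risk (so $RR \le 1+\alpha$), $\gamma \ge 0$ the rate of approach,
$\delta > 0$ the curvature near the counterfactual, and $z_{cf}$ is the
counterfactual concentration. Risk below the counterfactual is clamped to
exactly 1 — no extrapolated benefit, the standard CRA convention. The curve
is continuous and non-decreasing; both properties are enforced by tests on
a 1,000-point sweep over 0–500 µg/m³.

The Global Exposure Mortality Model (GEMM) is supported as an alternative
(`risk_model = "gemm"`), with hazard ratio
$HR(z) = \exp\{\theta \log(1 + \Delta z/\alpha_k)\,\omega(\Delta z)\}$,
$\Delta z = \max(z - z_{cf}, 0)$ and logistic weight
$\omega(\Delta z) = 1/(1+e^{-(\Delta z - \mu)/\nu})$. GEMM parameters are
user-supplied configuration; the package fits neither family
(curve-fitting is out of scope by design — published draw sets are
consumed as-is through the CSV schema of `read_curves()`).

### From risk to deaths

The population attributable fraction is $PAF = (RR-1)/RR$. Deaths in a
country stratum are apportioned to grid cells proportionally to cell
population (no sub-national mortality variation — baseline deaths are only
available at country level), so attributable deaths for a stratum with
baseline $D$ are

$$D \sum_i \frac{pop_i}{\sum_j pop_j}\, \mathrm{PAF}(RR(z_i)).$$

This makes attributable deaths exactly linear in baseline mortality and
invariant to rescaling all populations — two properties the acceptance
suite checks directly.

### Scenarios

A scenario replaces each cell's concentration with the cap wherever the
current level is higher: `pm25 := min(pm25, cap)`. The cap applies to grid
cells, not to country means; a country's population-weighted mean under a
scenario is therefore generally below the cap. (Published scenario
narratives sometimes describe the capped values as population-weighted
means; we keep the cell-wise rule as the single code path and note the
interpretation difference here rather than implementing a second one.)
Capping is idempotent and monotone in the cap, which yields the key
qualitative guarantee: percent reductions are non-decreasing along
IT1 → IT2 → IT3 → AQG for every stratum.

### Counterfactual (TMREL)

The theoretical minimum-risk exposure level is treated as uniformly
distributed, by default $U(2.4, 5.9)$ µg/m³ — the range used with the
GBD 2015 IER draws, reflecting genuine uncertainty about effects of
low-level exposure. One $z_{cf}$ is sampled per Monte-Carlo draw and
applied to **all** causes and **all** scenarios within that draw.

### Uncertainty: matched draws

`run_monte_carlo()` implements "matching random samples of each input
variable" as index-matched draws: draw $d$ pairs one sampled $z_{cf}$ with
the $d$-th parameter draw of every curve (cycled in `draw_id` order when
the table has fewer draws than `n_draws`), and uses the same pair for the
current grid and every capped grid. Index-matching is what makes the
scenario difference well-defined within a draw; percent reductions are
computed per draw, $r_d = 100(D_{cur,d}-D_{scen,d})/D_{cur,d}$, then
summarised. A consequence worth remembering when reading the tables: the
summarised percent reduction is a draw-level mean and need not equal the
ratio of the summarised death totals (the test suite pins this down with a
two-draw example where the two differ, 30% vs 33.3%).

Aggregation (country → WHO region → world) always sums the per-draw
vectors and summarises afterwards, never the other way round, so world =
Σ regions = Σ countries holds exactly per draw.

## Tunable parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `scenarios` | current, 35, 25, 15, 10 | µg/m³ | the 2005 WHO ladder; custom caps allowed |
| `cf` (TMREL) | U(2.4, 5.9) | µg/m³ | `low == high` gives a fixed counterfactual (GEMM uses its own fixed 2.4) |
| `n_draws` | 1000 | – | a configuration default, not a claim about any published run |
| `seed` | required | – | the only randomness is the TMREL sample; curve cycling is deterministic |
| `point` | `"mean"` | – | `"median"` available; published tables do not say which summary was used, so both are provided and the choice is recorded in the manifest |

Two modes cover the open question of how point estimates treat the
counterfactual: the default samples $z_{cf}$ for point and interval alike;
passing `counterfactual_spec(c, c)` reproduces a fixed-central-value
convention. Neither is asserted to be "the" convention of any particular
published computation.

## The synthetic world

`generate_world()` emulates the statistical structure of the real input
triplet so the pipeline runs and is tested offline:

* **Exposures**: cell concentrations are log-normal around each country's
  median with a country-specific log-scale dispersion — the simplest
  positive, right-skewed model consistent with published exposure
  surfaces. Dispersion 0 degenerates to "every cell at the median", which
  is what makes closed-form oracles exact.
* **Populations**: a symmetric Dirichlet(1) split of the country total
  across cells.
* **Mortality**: deterministic `round(rate × population × share)` counts
  (half-even), split over sex and age bands, so oracle tests are exact;
  `poisson_deaths = TRUE` adds count noise for robustness checks. Age
  bands are 25–49/50–69/70+ for the adult causes, plus 0–4/5–24 for LRI.
* **Curves**: central IER parameters per cause with multiplicative
  log-normal noise (default SD 0.1) across 100 draws per stratum. Central
  values were chosen once to give relative risks in the 1.1–1.6 range over
  10–100 µg/m³, the magnitude of published IER fits, with cardiovascular
  risk attenuating with age.

What the generator does **not** emulate: spatial autocorrelation of the
exposure surface, exposure-model calibration error, within-cell exposure
variation, or country-specific cause-rate structure (all countries share
the default per-100k rates). Passing tests therefore demonstrate the
correctness and invariances of the CRA machinery on data with the right
shape — not agreement with any country's actual burden.

The bundled preset (`preset_high_low_world()`) has five high-exposure
countries (medians 48–66 µg/m³, so every cap binds) and six low-exposure
ones (7–16 µg/m³, where at most the AQG binds). The USA-like country is
generated with dispersion 0 at 7 µg/m³ so that *every* cell is below
*every* cap and its reduction is exactly zero — the null regime — by
construction, not by sampling luck. Codes are mnemonic stand-ins, not
national statistics. Because three of the high-exposure countries have
deliberately close medians, their per-100k avoided-death ranks can swap
between generator seeds; the seed-invariant structure (high group above
low group, the steepest-exposure countries leading, zero for the USA-like
country) is what the tests assert.

## Numerical choices

* Degenerate inputs: zero-population countries, sub-unity relative risks,
  negative concentrations and negative caps are rejected with messages
  naming the offending field or cell; they always indicate an upstream
  problem rather than a representable state.
* A draw with zero current-level deaths makes the percent reduction for
  that unit undefined (`NA`), never 0.
* UIs are 2.5th/97.5th percentiles (`stats::quantile`, default type 7).
* Cells with zero population are retained through capping and I/O so
  files round-trip byte-identically.
* `0^δ` at the counterfactual boundary evaluates to 0 for δ > 0, so the
  clamped and analytic branches agree exactly at `z = z_cf`.

## Problem sizes

The test suite and the reproduction script are sized for interactive use:
the preset world has ~1,200 cells and 374 mortality strata; monotonicity
and conservation checks run at 100–200 draws, the quadrature oracle at
2,000 draws on a four-cell world, and the analysis scripts at 1,000 draws.
The engine is vectorised over cells × draws per country and curve stratum,
so these sizes complete in seconds; real-scale inputs (hundreds of
countries, ~10⁶ cells) stream through the same code path country by
country.

## Limitations

* Deaths only — no DALYs, years of life lost, or life-table modelling of
  gradual exposure reductions (an instantaneous-drop assumption).
* No joint correction for household air pollution co-exposure.
* Country-level mortality apportioned by population ignores within-country
  correlation between exposure and baseline rates.
* Exposure grids are consumed as given; cells must arrive with country
  codes already assigned (border-straddling cells are the provider's
  allocation decision).
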