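---
title: "Projecting lifetime morbidity and healthcare cost with stratified Markov chains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting lifetime morbidity and healthcare cost with stratified Markov chains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifecourse)
```

## The model

`lifecourse` projects the morbidity and healthcare cost of a population
over the whole life course from a longitudinal person-year registry. The
population is classified each year into six aggregated clinical risk
group (CRG) core health statuses — `E1` healthy, `E2` significant acute
disease, `E34` minor chronic disease, `E56` significant chronic disease
in one or two organ systems, `E79` significant chronic disease in three
or more organ systems / catastrophic conditions, `E8` dominant and
metastatic malignancies — plus an explicit absorbing death state `DEAD`,
for $m = 7$ states in a fixed order used everywhere in the package.

The central assumption is first-order Markov dynamics on a yearly grid:
the state of an individual in one year depends only on the state of the
year before. One-year transition probabilities are allowed to differ by
gender and by ten age bands ($<1$, $1{-}14$, $15{-}24$, …, $75{-}84$,
$\ge 85$), giving 20 row-stochastic $7\times7$ matrices. Within the
observation window the chain is assumed stationary (time-homogeneous);
this assumption is *tested*, not imposed blindly.

Age bands are half-open integer intervals $[lo, hi)$, so every completed
age maps to exactly one band, and the band of the *origin* year of a
transition determines the stratum — the transition probability
conditions on the state (and age) of the year before.

### Estimation

With the complete state sequence observed for the whole population,
the maximum-likelihood estimator of each transition probability is the
pooled count ratio

$$\hat p_{ij} \;=\; \frac{\sum_t n_{ij}(t)}{\sum_z \sum_t n_{iz}(t)},$$

where $n_{ij}(t)$ counts individuals in state $j$ at year $t$ that were
in state $i$ the year before, within a stratum. Persons observed in a
single year, or with a gap between observations, contribute no
transition: gaps are censoring (migration) and are never imputed.
Origin rows never observed in a stratum receive an identity fallback
row (stay in state) with a consolidated warning — the least-informative
choice that keeps every matrix stochastic — and the `DEAD` row is always
forced absorbing.

### The stationarity test

Stationarity is assessed per stratum by comparing per-period transition
frequencies $\hat p_{ij}(t)$ to the pooled $\hat p_{ij}$:

$$X^2 \;=\; \sum_t \sum_{i,j} n_i(t-1)\,
  \frac{\bigl(\hat p_{ij}(t) - \hat p_{ij}\bigr)^2}{\hat p_{ij}}.$$

Cells with pooled $\hat p_{ij} = 0$ contribute $0/0$ terms; they are
skipped and removed from the free-parameter count. Two degree-of-freedom
conventions are reported. `df_nominal` is the textbook $m(m-1)(T-1)$
with $T$ read as the number of observation years, i.e. $m(m-1)$ times
the number of period matrices; it is shown because it is the convention
most readers will look for. `df_adjusted` multiplies the actual number
of free parameters (structural zeros removed, at most $m-1$ per
observed row) by *periods minus one*, the classical convention for
comparing $P$ estimated matrices against their own pool — the pooled
matrix is itself estimated from the same counts, which consumes one
period's worth of parameters. The statistic is asymptotically
chi-squared only under the adjusted convention, so the p-value and the
stationarity decision use `df_adjusted`; simulation under a truly
stationary chain confirms the size of the test is near the nominal
level there and far below it under `df_nominal`. Note that $m(m-1)$
nominally includes the absorbing row, which has no free parameters; the
adjusted count drops it automatically because all its off-diagonal
pooled probabilities are zero. The test informs — strata that fail are
reported, but the pooled matrix is still used, since a single
non-stationary stratum does not invalidate a lifetime projection built
mostly from the others.

### Two complementary projection engines

**Cohort propagation** evolves the expected state occupancy of a closed
birth cohort (default 100,000) by repeated vector-matrix products,
switching stratum matrix at the band boundaries
$\{1, 15, 25, \ldots, 85\}$. The result is exact given the matrices: no
sampling noise, but no variability measures either. Occupancy jumps at
band boundaries are expected and are not smoothed — they are a property
of the band construction, not an artifact.

**Monte-Carlo microsimulation** draws individual birth-to-death
pathways (default 10,000 per gender) by comparing one pseudo-random
uniform per year against the cumulative transition probabilities of the
current row, scanning states in the fixed order with half-open
boundaries so every draw maps to exactly one destination. The pathway
collection yields the full distribution of lifetime quantities — SD,
skewness, kurtosis, quartiles — at the price of sampling error in the
means. On the same inputs the two engines must agree in expectation;
their relative gap at the default number of pathways is the standard
consistency check and is re-verified by the test suite and the
acceptance script.

Conventions shared by both engines, chosen once and applied
consistently:

* **Start-of-year occupancy.** A person alive at the start of a year of
  age contributes one full person-year in the state held at that start;
  the year of death contributes nothing beyond the preceding starts. No
  mid-year (half-cycle) correction is applied.
* **Termination.** Propagation stops when surviving mass falls below
  `extinction_tol` (default $10^{-6}$ of the cohort) and simulation
  stops at `max_age` (default 110), where any survivor is forced to
  die. The $\ge 85$ band never empties analytically, so a cap is needed
  for termination; at the defaults the truncated tail is negligible
  relative to the quantities reported. Tests that compare against the
  fundamental-matrix oracle $(I-Q)^{-1}$ at $10^{-6}$ tolerance tighten
  `extinction_tol` and raise `max_age` so that truncation, not the
  engine, is never the binding error.
* **Initial mix.** Both engines start from a probability distribution
  over (gender, transient state) at age 0, taken from the infant
  cross-section of the panel (pooled over years, since infants are
  scarce in any single year) or from the synthetic ground truth.

### Costs

Mean annual cost per (gender, state) cell — optionally refined by age
band where a cell has enough person-years — is attached to each
projected person-year; the cohort engine aggregates it over occupancy,
the microsimulation over individual pathways. Pathway years carry the
*cell mean*, not an individual draw, so the spread of the lifetime-cost
distribution reflects the variability of health transitions, not
cost-level noise within a cell. Yearly mean cost divides by survivors
at each age (ages past extinction are missing, not zero); whether a
per-capita denominator including the dead would be preferable is a
sensitivity the package leaves to the user, who can recompute it from
the occupancy output. Lifetime cost divides by the initial cohort, and
with age-invariant costs it equals the inner product of expected years
and cell costs — an identity the tests verify to $10^{-9}$.

Quartiles use linear interpolation between order statistics
(`quantile` type 7). Skewness is the third standardized central moment.
Kurtosis conventions differ across software, so both the raw fourth
standardized moment and its excess (raw minus 3) are reported and
labelled; neither is privileged.

## The synthetic registry generator

No individual-level registry of this kind is publicly deposited, so the
package ships a generator whose output has the statistical shape of a
county-level integrated-care population, with a *known* ground truth
against which estimation and projection are tested. The generator
enforces exactly the model's assumptions — first-order yearly dynamics,
explicit `DEAD` records, censoring by migration without a death record
— so parameter recovery is a clean test of the estimation code.

Calibration anchors, fixed at design time:

* cross-sectional healthy prevalence near 65%, and a forward-simulated
  healthy share within $[0.55, 0.75]$;
* a birth cohort that is ~96% healthy with a 50.5% male share;
* an infant acute-care peak, and an elevated healthy-to-acute
  transition for women in the 15–44 bands (default multiplier 1.5,
  motivated by pregnancy-related episodes; men instead carry a 1.3
  multiplier into the two most severe categories);
* severe-state (E79 + E8) population share below 1%, maintained by
  age-independent mortality floors (0.04 and 0.15 per year) on top of
  the age gradient — catastrophic conditions and metastatic
  malignancies have short sojourns at any age;
* baseline mortality growing geometrically across age bands (default
  factor 2.7 per band from $2\times10^{-5}$), which puts mid-life
  hazards and the resulting life expectancies on the scale of a
  contemporary southern-European life table; mortality is
  non-decreasing in age within every (gender, state) by construction;
* right-skewed annual costs from a gamma family parameterized by the
  cell mean and a coefficient of variation (default 1.5), with
  published-scale gender-by-state means (`reference_cost_means()`).

One root seed drives three independent sub-streams — population
structure and migration, state dynamics, costs — so regenerating costs
never perturbs state paths. Migration defaults (2% per year in and out)
are arbitrary: no quantitative rates were available to calibrate them,
and they exist to exercise the censoring logic, not to model mobility.

What the generator does **not** emulate, and hence what passing tests
do not show about real data: there is no infant-mortality peak (the
monotone-mortality guarantee excludes it); no births during the window
(infants enter only through pyramid-shaped in-migration, which is why
the initial-mix estimator pools years); no within-cell cost
heterogeneity correlated with state history; no secular trends — the
generated chain is exactly stationary, so the stationarity test's power
against real drift is not exercised; and no structural zeros beyond the
absorbing row. Real registries will violate several of these.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `cohort_size` | 100,000 | persons | standard reporting cohort; results scale linearly |
| `n_per_gender` | 10,000 | pathways | puts the MC mean within a fraction of a percent of the exact value while keeping runtime in seconds |
| `max_age` | 110 | years | termination cap; forced death beyond it |
| `extinction_tol` | 1e-6 | fraction | surviving-mass cutoff of the cohort engine |
| `alpha` | 0.05 | — | stationarity decision level |
| `min_cell` | 30 | person-years | minimum cell size for an age-refined cost mean |
| `age_mortality_gradient` | 2.7 | per band | geometric hazard growth across bands |
| `female_acute_multiplier` | 1.5 | — | excess female acute risk at 15–44 |
| `cost_cv` | 1.5 | — | gamma coefficient of variation of annual costs |

## Numerical choices and degenerate inputs

Row-stochasticity is validated to $10^{-10}$ on construction and before
any propagation; matrix files round-trip probabilities at 12 decimals
and are re-normalized only within that fuzz (a genuinely non-stochastic
file is rejected, not rescued). Inverse-CDF boundaries are half-open
with the final cumulative pinned to 1, so a uniform draw always maps to
exactly one state. Degenerate inputs have defined behavior: an
all-identical cost sample reports `SD = 0` and missing skewness and
kurtosis; an age with zero survivors yields a missing yearly cost; a
single-year panel, a transition out of `DEAD`, and a non-summing
initial mix are errors, not silent fixes.

The test suite exercises the full stack at reduced problem sizes chosen
to keep the default run fast while leaving no code path untested:
parameter recovery on a 50,000-person, 4-year panel; engine agreement
at the full default sizes (100,000 cohort, 10,000 pathways per gender);
stationarity calibration on a 3-state chain with 2,000 individuals and
200 replicates; fundamental-matrix oracles on 2–6-state toy chains.

## Known limitations

* A projection from a fixed transition pattern assumes the observed
  window's probabilities hold for a century of simulated life; death
  probabilities in particular have been falling for decades, so
  projected life expectancies are best read as "if current transitions
  persisted".
* Costs are attached as constant 2007-euro cell means: no discounting,
  no growth scenarios, no time-to-death cost gradient. These are
  deliberate exclusions, not oversights.
* The CRG grouping itself (diagnosis codes to health states) is
  upstream of this package; states are taken as given.
* The stationarity test is asymptotic; in strata with few person-years
  (infants, the oldest bands) the chi-squared approximation is rough,
  which is another reason the test informs rather than gates.
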