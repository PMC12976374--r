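---
title: "Probabilistic dietary PAH4 exposure and the cancer burden chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic dietary PAH4 exposure and the cancer burden chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pahburden)
```

## The problem

Polycyclic aromatic hydrocarbons (PAHs) form in food during high-temperature
cooking and processing; benzo[a]pyrene is a Group 1 carcinogen and the summed
concentration of benz[a]anthracene, benzo[a]pyrene, benzo[b]fluoranthene and
chrysene — **PAH4** — is the EU marker for PAH contamination of food.
`pahburden` implements a full population-level assessment of dietary PAH4
intake from total-diet-study (TDS) style data: a two-scenario Monte Carlo
simulation of acute intake, distributional characterisation, cluster-based
classification into exposed and unexposed sub-populations, and the
lifetime-cancer-risk / attributable-fraction / DALY burden chain.

A TDS measures contaminants in *composite samples*: foods are purchased,
prepared to a table-ready state, pooled across brands and origins, and
analysed once per composite. Consumption comes from a 24-hour recall survey
encoded as grams of food per kilogram of body weight per day, so body weight
never appears as a separate variable. The atomic unit of the simulation is
the **person-day**: one individual's complete 24-hour diet.

## The exposure model

Each Monte Carlo iteration:

1. draws one surveyed person-day uniformly with replacement;
2. for each food in that diet, draws one of the food's composite samples
   uniformly — the *same* sample index for all four analytes, because the
   analytes were measured on the same physical composite and independent
   per-analyte draws would destroy within-sample correlation;
3. substitutes non-detects according to the scenario (below), sums the four
   analyte concentrations into PAH4 (µg/kg), and accumulates

$$E = \sum_{\text{events}} a_i \,[\mathrm{PAH4}]_i \times 10^{-6}
\quad \text{mg/kg bw/d},$$

where $a_i$ is the consumption amount in g/kg bw. Concentrations are held in
µg/kg everywhere and exposures reported in mg/kg bw/d; the single $10^{-6}$
conversion lives in `person_day_exposure()` and nowhere else, which keeps
unit errors structurally impossible rather than merely tested for.

The default 100,000 iterations give a stable frequency distribution: across
independent root seeds the medians of repeated runs on the default synthetic
data agree to well under 1% (the test suite enforces 2%).

### Left-censored measurements and the two scenarios

Most sample × analyte measurements in PAH TDS data are below the limit of
detection (LOD). Rather than pick one substitution rule, the package brackets
the truth with two:

* **optimistic** (lower bound): non-detects count as 0 µg/kg;
* **pessimistic** (upper bound): non-detects count as their record's LOD
  (0.15 µg/kg in the synthetic data).

Every concentration record carries its own LOD, so the upper bound is
data-driven per record rather than a global constant. With
`common_random_numbers = TRUE` (the default) both scenarios reuse the same
person-day and sample draws, so the pessimistic exposure dominates the
optimistic one *pathwise* — at every single iteration — since substitution is
the only difference between the runs. This coupling is what makes the
scenario gap interpretable as pure censoring uncertainty instead of Monte
Carlo noise.

Surveyed foods with no concentration record contribute zero exposure and emit
one warning per food: zero-fill is the only choice that cannot inflate the
lower bound.

## Characterising the distribution and classifying exposure

`summarize_distribution()` reports range, median, 95th percentile, the
fraction of strictly positive values, and kurtosis in the **Pearson
(non-excess) convention** $m_4/m_2^2$, under which a normal distribution
scores 3. The convention matters for interpretation: lower-bound substitution
produces a point mass at zero plus a heavy right tail (kurtosis ≫ 3,
leptokurtic), while upper-bound substitution fills the floor in and pulls the
shape toward normal.

"Positive exposure" has two defensible readings and the package computes
both: the strictly-greater-than-zero fraction (meaningful for the optimistic
scenario, where non-detects genuinely contribute nothing) and the
exposed-cluster share below (the only reading available to the pessimistic
scenario, whose support is strictly positive). The burden chain consumes the
cluster-based prevalence.

### Exact one-dimensional two-means

Exposure prevalence is the fraction of simulated person-day draws in the
higher-mean of two clusters. In one dimension every optimal two-means
partition is an interval split, so `kmeans_two()` finds the *global* optimum
by scanning all $n-1$ sorted-order cut points with cumulative sums — no
initialisation, no iteration, $O(n \log n)$. This choice is deliberate:
iterative k-means is sensitive to initialisation on outlier-heavy data, and
we confirmed empirically that plain Lloyd iteration from random data-point
starts misses the global optimum on 5–13% of heavy-tailed lognormal samples
(the optimum often isolates a few extreme values whose attraction basin is
tiny). The multi-start Hartigan–Wong cross-check (`kmeans_two_lloyd()`,
whose converged solutions are Lloyd fixed points) agrees with the exact
solver on 100/100 random samples in the acceptance suite, and a naive
$O(n^2)$ brute-force oracle independently verifies the cumulative-sum
arithmetic in the unit tests.

The cluster contrast is verified with a Mann-Whitney U test;
Shapiro-Wilk (per group) and Levene (Brown–Forsythe variant, via `car`)
check the non-normality and variance-heterogeneity assumptions. Assumption
checks warn but never abort — they are verification, not gates. Shapiro-Wilk
is limited to $n \le 5000$, so larger inputs are thinned deterministically to
5000 evenly spaced order statistics; the thinning preserves the empirical
distribution and avoids a second seed. Cooking-method differences in
per-sample PAH4 within a food category are tested with Kruskal-Wallis, using
pessimistic substitution because lower-bound substitution collapses
all-non-detect methods to identical zeros and degenerates the test.

## The burden chain

From the median exposure $E$ of a scenario's frequency distribution:

$$R = E \cdot SF_{avg} \cdot \frac{t_{exp}}{L}, \qquad
RR = 1 + \frac{R}{T - R}, \qquad
PAF = \frac{p\,(RR-1)}{p\,(RR-1)+1}, \qquad
D = PAF \cdot D_{tot},$$

with $SF_{avg}$ the averaged slope factor ((mg/kg bw/d)^-1^), $t_{exp}$ the
adult exposure window (life expectancy 83 − minimum survey age 18 = 65
years), $T = 0.25$ the total lifetime cancer risk, $p$ the exposure
prevalence, and $D_{tot}$ the all-cancer DALY total of the reference
population. The median exposure is also compared against a PAH4 minimal risk
level (MRL, default $4.84\times10^{-4}$ mg/kg bw/d; exposures equal to the
MRL classify as "below").

Two modelling choices here deserve their reasons:

* **The relative risk is the excess-risk reading** $1 + R/(T-R)$, not the
  bare ratio $R/(T-R)$. The bare ratio of a small attributable risk to the
  remaining background is far below 1, which would make Levin's $(RR-1)$
  term negative and the attributable fraction meaningless; reading $R$ as
  *excess* risk on top of the shared background $T-R$ keeps $RR \ge 1$ and
  makes the chain self-consistent. The bare ratio remains available as
  `relative_risk_literal()` for inspection.
* **Slope-factor averaging is explicit.** The default is the arithmetic mean
  of the four per-analyte slope factors (BaA $10^{-1}$, BaP $10^{1}$, BbF
  $10^{-1}$, Ch $10^{-3}$; mean 2.55025). Because the mean of published
  per-analyte potencies and the effective potency an assessment actually
  uses need not coincide, `sf_avg_method = "fixed"` imposes any explicit
  value; the consistency tests exercise this with an effective value of
  ≈ 0.300 back-solved from a known exposure→risk pair and confirm a single
  value reproduces a second independent pair to three significant figures.
* **`total_cancer_dalys` has no default.** It is a population statistic of a
  reference year, not a model constant, and silently defaulting it would
  invite mismatched DALY totals; callers supply it (158,418 all-cancer DALYs
  for the 2021 reference population in the analysis scripts).

`cancer_risk()` rejects results ≥ 1 outright: a lifetime probability that
overflows signals a unit error (most plausibly µg-vs-mg) rather than a large
risk, and refusing is safer than clamping.

## The synthetic data generator

The real TDS microdata behind this kind of assessment are typically not
deposited, so `synth_config()` + `generate_*()` produce datasets with the
statistical structure the pipeline assumes, sized like the real study: 21
food categories over 264 foods, 2 composite samples per food (the study's
480 composites over 264 foods is a non-integer ratio, so samples-per-food is
a free parameter), and 2,000 respondents.

Defaults chosen where the study conditions leave freedom, fixed once:

| parameter | default | why |
|---|---|---|
| `detect_rate` | 0.05 | PAH4 non-detect rates in TDS data are typically well above 90% |
| `conc_log_mean`, `conc_log_sd` | log(0.5), 1.0 | detected medians ~0.5 µg/kg with a heavy right tail; reproduces the leptokurtic lower-bound exposure (kurtosis ≈ 36 on default data) |
| `lod` | 0.15 µg/kg | the upper-bound substitution value |
| `foods_per_day_mean` | 10 | a plausible count of distinct foods in a 24-hour recall |
| `amount_log_mean`, `amount_log_sd` | log(1.5), 0.8 | ~100–150 g portions for a 60–80 kg adult, right-skewed |
| ages | uniform 18–83 | survey minimum age to life expectancy; age is unused downstream |

`generate_bimodal_sample()` is a separate fixture for the clustering stage:
a zero-truncated two-component normal mixture with enforced separation
(`low_mean + 4·sd < high_mean`), whose component labels serve as ground
truth for prevalence recovery.

What the generator does *not* emulate — and therefore what passing tests do
not show about real data: the survey's age/ethnic stratification, true
per-category concentration profiles, correlation between food choices within
a diet, seasonal or regional variation, and any dependence of detection
probability on food category. Tests on synthetic data validate the
*machinery* (coupling, units, estimators, the burden algebra), not the
field values of any real population.

## Numerical and degenerate-input conventions

* All generators and the simulator are deterministic functions of
  `(config, seed)`; decoupled scenario streams derive a labelled sub-seed
  from the root seed.
* Two-means requires ≥ 2 distinct values; kurtosis requires ≥ 4 values and a
  nonzero second moment — constant inputs are errors, not NaNs.
* The two-means threshold is the midpoint between the two cluster-adjacent
  sorted values; ties on the threshold go to the unexposed side.
* CSV writers emit doubles at 17 significant digits, so a write/read cycle
  reproduces every field bit-for-bit.
* Percentiles use linear interpolation (R's default type-7 quantiles).

## Problem sizes

The test suite runs the full study scale where the property demands it
(100,000 iterations for pathwise dominance and median stability; 10,000
draws for mixture recovery; 100 samples for the clustering oracle) and
shrunk-but-structured configurations (30 foods, 150 respondents, 500–3,000
iterations) everywhere the property is scale-free. The complete suite runs
in well under a minute.

## Known limitations

* Acute (single-day) exposure only: person-day resampling captures
  between-day and between-person variability but says nothing about
  long-term average intake for any individual.
* The burden chain treats PAH4 as one combined carcinogen against all-cancer
  DALYs; no per-analyte cancer-site attribution is attempted.
* Protective exposures (RR < 1) are out of scope for Levin's formula as
  implemented.
* The MRL is a configuration constant; its derivation from per-congener
  toxic-equivalency scaling is upstream of this package.

## A minimal run

```{r example, eval = FALSE}
rp <- risk_params(total_cancer_dalys = 158418)
cfg <- pipeline_config(synth = synth_config(seed = 1L),
                       iterations = 100000L, seed = 1L, risk = rp,
                       output_dir = "run1")
report <- run_pipeline(cfg)
report$scenarios$pessimistic$burden$paf
```

The numbered scripts under `analysis/` run the same chain stage by stage,
writing every intermediate table under `results/` so each reported number is
traceable to a file.
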