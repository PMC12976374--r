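# pahburden

Probabilistic assessment of dietary exposure to the four EU marker
polycyclic aromatic hydrocarbons (**PAH4**: benz[a]anthracene,
benzo[a]pyrene, benzo[b]fluoranthene, chrysene) from total-diet-study (TDS)
style data, and estimation of the attributable cancer burden. Built for risk
assessors and food-safety epidemiologists who have (or need to emulate) a
TDS concentration table and a 24-hour-recall consumption survey and want a
tested, reproducible path from raw tables to an attributable-DALY figure.

## What it computes

**Exposure.** A Monte Carlo simulation resamples surveyed person-days
(uniformly, with replacement) and composite-sample concentrations (one
sample index per food and iteration, shared across the four analytes),
summing

    E = Σ_events  amount (g/kg bw) × [PAH4] (µg/kg) × 10⁻⁶   mg/kg bw/d

over each sampled 24-hour diet, 100,000 iterations per scenario. Left-
censored measurements are bracketed by two coupled scenarios — **optimistic**
(non-detect = 0) and **pessimistic** (non-detect = LOD, 0.15 µg/kg by
default) — sharing common random numbers, so the pessimistic run dominates
the optimistic one at every single iteration and the gap between them is
pure censoring uncertainty.

**Classification.** Exposure prevalence comes from exact one-dimensional
two-means clustering (global optimum by sorted cut-point search, immune to
the initialisation sensitivity iterative k-means shows on outlier-heavy
exposure data), verified by Mann-Whitney with Shapiro-Wilk/Levene assumption
checks; cooking-method contrasts use Kruskal-Wallis.

**Burden.** From a scenario's median exposure E and prevalence p:

    R   = E · SF_avg · t_exp / L          lifetime cancer risk
    RR  = 1 + R / (T − R)                 relative risk (excess-risk reading)
    PAF = p(RR−1) / (p(RR−1) + 1)         Levin's attributable fraction
    D   = PAF · D_total                   attributable DALYs

with slope factors per analyte (BaA 10⁻¹, BaP 10¹, BbF 10⁻¹, Ch 10⁻³),
exposure window t_exp = 83 − 18 = 65 years, total lifetime cancer risk
T = 0.25, and a minimal-risk-level comparison (MRL 4.84 × 10⁻⁴ mg/kg bw/d).

A synthetic TDS generator (21 categories, 264 foods, 2,000 respondents,
heavily left-censored lognormal concentrations) stands in for real
microdata, making every stage testable end to end.

## Worked example

The numbered scripts under `analysis/` run the whole chain on the default
synthetic TDS:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_exposure_stats.R
Rscript analysis/03_risk_burden.R
```

which prints (stage 1 and 2):

```
synthetic TDS: 264 foods in 21 categories, 528 composite samples, 2000 respondents
non-detect rate: 94.6% of sample x analyte measurements
optimistic  median 2.23e-06, range [0, 0.000101] mg/kg bw/d
pessimistic median 1.44e-05, range [1.16e-06, 0.000113] mg/kg bw/d
pathwise dominance (pessimistic >= optimistic): TRUE
optimistic  kurtosis 36.2 | positive (>0) 86.2% | exposed cluster 10.4% | MW p 0
pessimistic kurtosis 13.7 | positive (>0) 100.0% | exposed cluster 25.3% | MW p 0
```

The two scenarios bracket the acute intake of the simulated population; the
optimistic distribution is strongly leptokurtic (kurtosis 36.2 in the
Pearson convention, normal = 3) because zero-substitution leaves a point
mass at zero plus a heavy detected tail, while LOD-substitution fills in the
floor and pulls the shape toward normal. Stage 3 then runs the burden chain
on each scenario's median and prevalence:

```
SF_avg (arithmetic mean) = 2.55025 per mg/kg bw/d; exposure window 65 years
optimistic  median 2.23e-06 mg/kg bw/d (below MRL) -> risk 4.46e-06, PAF 1.85e-06, DALY 0.293 y
pessimistic median 1.44e-05 mg/kg bw/d (below MRL) -> risk 2.87e-05, PAF 2.9e-05, DALY 4.6 y
published-input chain: SF_avg = 0.3001, PAF 1.64e-05 (optimistic) / 0.00642 (pessimistic)
```

Both scenario medians sit below the MRL and the attributable fractions are
tiny — dietary PAH4 in data of this shape is a minor contributor to total
cancer burden. The `published-input chain` line evaluates the same algebra
on published exposure/risk/prevalence values, with the effective slope
factor back-solved from one exposure→risk pair reproducing the other.

Equivalent programmatic entry point:

```r
library(pahburden)
rp  <- risk_params(total_cancer_dalys = 158418)
cfg <- pipeline_config(synth = synth_config(seed = 1), iterations = 100000,
                       seed = 1, risk = rp, output_dir = "run1")
report <- run_pipeline(cfg)
```

## Package layout

- `R/` — the implementation: TDS table I/O and validation (`tds_data`),
  synthetic generator (`synthetic_tds`), Monte Carlo engine
  (`exposure_sim`), distribution statistics and clustering (`dist_stats`),
  the burden chain (`risk_burden`), and pipeline orchestration.
- `analysis/` — numbered narrative drivers writing under `results/`.
- `vignettes/pah4-exposure-burden.Rmd` — the model, its assumptions, all
  tunable parameters, and known limitations.
- `tests/testthat/` — unit, property and acceptance tests (oracle-first:
  hand arithmetic, brute-force solvers, closed-form moments, sampling-error
  bands).
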