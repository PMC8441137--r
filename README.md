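# reproaudit

Staged Bayesian models for auditing the reproducibility of a research
literature.

Reproducibility audits sample published papers and walk each one through a
conditional pipeline: can the underlying **data be recovered** (online or
from the authors)? If so, are they **usable**? Is the published analysis
**clear** enough to repeat? And does the re-computed result **agree** with
the published one? Each stage is conditional on all previous ones, so the
probability that a result of a randomly chosen paper reproduces is the
product of four stage probabilities,

```
p(r) = p1 * p2 * p3 * p4 .
```

reproaudit implements the two model families such audits need, a
synthetic-audit generator, and the reporting layer that combines them:

* **Stage 1 — data decay.** Recovery is Bernoulli with probability
  `alpha_Y * exp(-lambda_Y * age)` per study type *Y* (human/non-human ×
  experimental/observational): `alpha` is recovery at publication,
  `lambda` a yearly decay rate, and `log(2)/lambda` the **data
  half-life**. A logistic-link alternative (`fit_stage1(link =
  "logistic")`) and a WAIC comparison (`compare_links()`) probe the
  exponential assumption.
* **Stages 2–4 — conditional hierarchical binomials.** Per-paper counts
  passing each stage, with `logit(p_s) = phi_s + beta_paper +
  gamma_year`: Normal paper effects capture the strong within-paper
  correlation of results, and a Gaussian-process smoother over
  publication year replaces any parametric age trend.
* **Inference and diagnostics.** MCMC via JAGS (4 chains × 2500 retained
  draws by default, fully seeded), rank-normalised split R-hat, Geyer
  effective sample sizes, narrowest (highest-density) 89% intervals,
  prior-predictive simulation, and reports that refuse to print when any
  diagnostic flags.
* **Synthetic audits.** `simulate_audit()` draws complete audits (560
  papers, 1955–2018, a 40-paper reproduction subsample with ~111
  results) from the generative model, returning the latent paper and
  year effects for parameter-recovery studies;
  `adequacy_simulation()` runs the simulate-and-fit coverage study that
  justifies a subsample size.

Everything is tibble-first and pipe-friendly, with `tidy()`/`glance()`
methods for fitted objects and `autoplot()` methods for the decay curve,
posterior densities and half-life table.

## Worked example

Simulate an audit at the default operating point (which encodes a
published audit of the social-learning literature), fit both model
families and combine them:

```r
library(reproaudit)

sim <- simulate_audit(seed = 42)
summarize_counts(sim$data)
#> Audit margins
#>   papers:            560
#>   online:            64 (11%)
#>   received:          112 (20%)
#>   lost:              194 (35%)
#>   no_response:       165 (29%)
#>   no_request:        25 (4%)
#>   recovered:         176 (31%)
#>   author responses:  306 (55%)
#>   reproduction subsample: 40 papers
#>   results_identified: 127
#>   data_usable:       112
#>   analysis_clear:    106
#>   results_agree:     102

ctrl <- mcmc_control(chains = 4, iter = 1250, warmup = 1000,
                     adapt = 500, seed = 43)
f1   <- fit_stage1(sim$data, control = ctrl)
f234 <- fit_stages(sim$data, control = ctrl)
report <- audit_report(f1, f234, reference_year = 2019)
report$converged
#> [1] FALSE
```

At these reduced settings a few weakly identified year effects fall under
the effective-sample-size threshold, so the report flags itself and will
not print without an override — that is the intended guardrail:

```r
print(report, force = TRUE)
#> Reproducibility audit report (89% narrowest intervals)
#>   p1_recovery    0.30 (0.27-0.32)
#>   p2_usability   0.88 (0.84-0.93)
#>   p3_clarity     0.94 (0.90-0.98)
#>   p4_agreement   0.96 (0.93-0.99)
#>   p_r_combined   0.24 (0.21-0.26)
#> Data half-life (years):
#>   human_experimental       9.7 (7.4-12.0)
#>   human_observational      9.3 (4.0-14.4)
#>   nonhuman_experimental    6.9 (5.6-8.0)
#>   nonhuman_observational   4.3 (2.8-5.9)
#>   pooled                   7.0 (6.1-8.0)
#> Overall success in 2018: 0.61 (0.54-0.69)
```

Reading the output: data for only 30% of the sample are recoverable, and
recovery is the binding constraint — conditional on it, usability,
clarity and agreement are all high — so only about one result in four
reproduces overall, while a paper published in the most recent year
(whose data have barely begun to decay) reproduces at around 0.6. Data
for human experimental studies halve every ~10 years, non-human
observational data every ~4 (here the generative truths were 9.6 and 4.5
years). Per-parameter summaries come from `tidy(f1)`, `tidy(f234)`,
diagnostics from `f1$diagnostics`, figures from `autoplot(f1)`,
`autoplot(report)` and `plot_half_lives(f1)`.

`run_pipeline()` wraps the same flow (read or simulate → fit → diagnose →
report) behind one config list or YAML file and serialises every
artifact — input tables, flat posterior CSVs, diagnostics and a
machine-readable `summary.json` — with the seed echoed.

## Package layout

| file | contents |
|---|---|
| `R/audit-data.R` | audit schema, CSV round-trip, count bookkeeping |
| `R/simulate.R` | synthetic-audit generator, adequacy simulation |
| `R/stage1.R` | decay model: likelihood, fits, half-life, predictions |
| `R/stages.R` | hierarchical stage models, GP kernel, marginalisation |
| `R/diagnostics.R` | R-hat, ESS, HPDI, convergence reports |
| `R/priors.R` | prior constructors, prior-predictive simulation |
| `R/report.R` | combined rate, by-year success, pipeline orchestration |
| `vignettes/reproducibility-audit.Rmd` | model and design notes |

The methods vignette documents the model assumptions, prior choices,
non-centred parameterisation, quadrature accuracy, and exactly what the
synthetic generator does and does not emulate.
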