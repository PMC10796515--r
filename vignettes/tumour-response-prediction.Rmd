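---
title: "Predicting radiotherapy response from weekly tumour volumes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting radiotherapy response from weekly tumour volumes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`radresp` predicts how an individual patient's gross tumour volume (GTV)
will evolve over a course of fractionated radiotherapy, using only the
sparse, noisy weekly CT measurements that routine care produces. This
vignette is the package's own account of the model, the statistical
machinery, and the design decisions that were genuinely open.

## The two-compartment model

All volumes are fold changes of the patient's initial GTV, so the initial
total volume is 1 and the carrying capacity `K` is expressed relative to
the initial tumour size. The tumour is split into living volume $L$ and
necrotic debris $N$; only their sum $V = L + N$ is observed on CT. Living
cells grow logistically at rate $\lambda$ (d$^{-1}$) towards $K$, undergo
spontaneous necrosis at rate $\eta$ (d$^{-1}$), and necrotic material
clears at rate $\zeta$ (d$^{-1}$). A radiotherapy fraction at time $t_i$
acts on a much faster timescale than growth and is modelled as an
instantaneous transfer of a volume $\gamma L$ from living to necrotic;
the GTV is therefore continuous across dose instants, and a response
becomes visible only through the subsequent clearance of the transferred
debris. The initial composition is `L(0) = 1 - phi0`, `N(0) = phi0`.

Two compartments are the minimum that reproduces all four response
shapes seen clinically: a one-compartment model cannot produce a
plateaued response (tumour shrinks then stalls at a sizeable volume,
driven by slow debris clearance) or pseudo-progression (continued
apparent growth before a delayed decline, driven by a large necrotic
fraction and strong but initially invisible cell kill).

### The dose impulse convention

The delta-function dosing term admits two readings: the literal transfer
`L+ = (1 - gamma) L-` used here as the default, and the limit of
integrating `dL/L` through the impulse, `L+ = exp(-gamma) L-`. They agree
to first order in `gamma` and both conserve volume. The convention is
isolated in `apply_dose()` and selectable everywhere via
`convention = c("transfer", "exponential")`; the package default is the
transfer form because it matches the verbal definition of `gamma` as the
fraction of living volume killed per fraction. Prior-predictive response
proportions under the two conventions differ by only a few tenths of a
percentage point.

### Numerical integration

Between events the system is smooth and non-stiff over the whole prior
support, and is integrated with an adaptive Dormand–Prince RK5(4) scheme
(compiled) at relative/absolute tolerances `1e-8`/`1e-10`. Tests verify
agreement with the logistic closed form and with an independent reference
integrator (`deSolve::lsoda` at tighter tolerances) to `1e-8` relative
error, volume conservation at dose instants to machine precision, and
invariance of results to splitting the time grid. Observations that
coincide with a dose report the post-dose compartment split; the total
volume is unaffected either way. Step-size collapse (possible only for
pathological states) is reported as a failure and, inside the likelihood,
maps to a log-likelihood of `-Inf` so the particle is discarded rather
than silently mis-simulated.

## Response classification

A model realisation is classified on a *standard patient*: weekday doses
for six weeks with measurements at the start of each treatment week and
at the final dose. Measurements are normalised to the volume at the start
of treatment, and with thresholds configurable via
`classification_thresholds()`:

* **poor responder** — all measurements above 85% of the
  start-of-treatment volume;
* **pseudo-progressor** — a responder whose second post-onset measurement
  exceeds 102% of the first;
* **plateaued** — a responder, not pseudo-progressing, with final
  measurement above 20% and final rate-of-change below 10% of the maximum
  rate-of-change;
* **fast responder** — any remaining responder.

"Rate-of-change" is not defined more precisely by the criteria's source,
so the package takes the magnitude of successive finite differences of
the measurement series divided by the time gaps; "final" is the last such
difference and "maximum" the largest magnitude. The thresholds were
calibrated on a small cohort and are deliberately configuration, not
constants.

**Anchoring.** `standard_schedule()` defaults to `start_day = 0`:
classification treats model time zero as treatment onset, so `phi0` is
the necrotic proportion at the start of treatment and the normaliser is
exactly 1. The alternative — initialising the composition at a diagnosis
scan two weeks before treatment and normalising to the evolved volume at
onset — systematically shifts the prior-predictive class proportions
(the necrotic fraction partially clears before the normaliser is taken,
depressing the apparent response rate by roughly 3–4 percentage points
under the box prior). The onset-anchored timeline reproduces the
published prior-predictive eventual-response probability and is used
throughout; records with a pre-treatment diagnosis scan (needed for
pre-treatment prediction replays) are built explicitly with
`standard_schedule(start_day = 14)`, and their pre-onset measurements are
flagged and excluded from classification.

## Observation model and noise pre-estimation

CT measurements are independent Gaussians centred on the model volume
with standard deviation linear in volume,
$\sigma(V) = \alpha_1 + \alpha_2 V$: an absolute floor plus a relative
term. The same parameters apply to necrosis measurements when a record
carries them (the joint-measurement scenario); no separate necrosis noise
model is introduced because none is identified by GTV-only data. Noise
draws are plain Normals — synthetic volumes may occasionally go negative
at very small tumour sizes, and they are kept, because the likelihood is
an untruncated Normal and truncating the generator would bias the
calibration checks.

The noise parameters are shared across patients and pre-estimated once:
each cohort patient is fitted with an 8-parameter MCMC (the six dynamical
parameters plus $\alpha_1, \alpha_2$ under independent `U(0, 0.5)`
priors — volumes are order 1 in fold-change units, so noise standard
deviations beyond 0.5 are implausible), an equal number of
$(\alpha_1, \alpha_2)$ samples per patient is pooled, and the estimate is
the joint marginal mode of a 2-D Gaussian KDE (Silverman bandwidths,
200-point grid per axis). They are then frozen for all subsequent
inference, which keeps the particle filter valid (it cannot distinguish
parameters that vary between patients from ones that do not).

## Inference

**Per-patient posteriors.** Robust adaptive Metropolis in log-parameter
space: the proposal's Cholesky factor receives a rank-one update each
iteration steering the acceptance rate to 0.234. Box-prior bounds act by
rejection. Chains start at independent prior draws (the box guarantees
valid starts). Defaults are 4 chains of 25,000 iterations, first half
discarded, thinned to 2,500 pooled draws per patient; split-$\hat R$ and
per-chain acceptance are always computed, and `check_convergence` chooses
between warning (default) and hard error at $\hat R > 1.05$ — a warning
is the default so one slow chain does not abort a whole cohort training
run, but the diagnostics always travel with the samples.

**Pooling and the second-level prior.** The population-level posterior is
the uniform mixture of per-patient posteriors (equal sample counts
enforced). For new patients this pooled set is expanded by resampling
particles and perturbing each with a
$\mathcal N(0, \Sigma_\varepsilon)$ kernel,
$\Sigma_\varepsilon = \beta\,(4 / (m(d+2)))^{1/(d+4)}\,
\mathrm{diag}(\Sigma_\theta)$ with $d = 6$ and $\beta = 2$ — Silverman's
KDE rule inflated to admit new patients not represented in a 40-patient
training set. Perturbations are redrawn (keeping the base particle) until
they land inside the first-level box, i.e. the kernels are truncated
multivariate normals; a redraw cap guards against base particles whose
kernel mass lies almost entirely outside the box. At $\beta = 0$ the
construction degenerates to a plain bootstrap resample, which tests
exploit.

**Filtering.** New-patient posteriors are bootstrap-filter reweightings
of the second-level prior: `weight ∝ prior weight × likelihood`. The
parameters are static, so incremental weekly updates recompute weights
from the complete record — this is exact, avoids resampling noise, and
makes batch and incremental filtering identical to machine precision
(asserted in tests). The effective sample size $1/\sum w^2$ is attached
to every filtered set; all weights vanishing raises a degeneracy error
(the prior does not cover the patient). For a record whose only
measurement precedes treatment, the model volume is exactly 1 for every
parameter vector, so the filter provably returns the prior — the
pre-treatment prediction *is* the second-level prior, as the workflow
tests assert.

## Prediction outputs and evaluation statistics

Trajectory and final-volume summaries are weighted means with 50% and 95%
bands. Mean-level bands use weighted quantiles via the left-continuous
inverse of the weighted empirical CDF; observation-level bands instead
invert the weighted mixture of Gaussian predictive CDFs numerically, so
they include measurement noise. Class probabilities are weight-sums over
the classified particles.

Goodness-of-fit uses the Bayesian $R^2$: per posterior sample,
$\mathrm{Var}(V_\mathrm{fit}) / (\mathrm{Var}(V_\mathrm{fit}) +
\mathrm{Var}(V_\mathrm{fit} - V_\mathrm{obs}))$, reported as the median
over samples. Variances are sample ($n-1$) variances — the ratio makes
the choice nearly immaterial, but it is fixed for determinism. The
degenerate 0/0 case (constant fit, zero residuals) is defined as 0 with a
warning. Cohort-level class comparisons use Welch's unequal-variance
$t$-test computed from summary statistics; class counts are fractional
under probabilistic classification, and the Welch–Satterthwaite degrees
of freedom are used without rounding (the $t$ CDF accepts fractional df
through the regularised incomplete beta function).

The default prediction horizon is three days after the final dose —
day 56 for a schedule ending on day 53 — and is configurable.

## The synthetic-data generator

`generate_patient()` draws a parameter vector from a chosen source (box
prior or particle set), simulates the noise-free measurement series under
its schedule, adds observation noise, and stores the true parameters and
true class. Class-conditional patients are produced by rejection on the
parameter draw only — the noise model is never adjusted — so conditional
cohorts remain exactly distributed as the source restricted to the class.
Fixture noise defaults to $(\alpha_1, \alpha_2) = (0.05, 0.10)$, a
mid-range value under the `U(0, 0.5)` noise priors; every synthetic
cohort records its seeds, noise parameters and true parameters in a JSON
manifest.

What the generator emulates: parameter heterogeneity from a population
distribution, weekday dosing, weekly measurement cadence, and
volume-dependent Gaussian measurement error. What it does not emulate:
CT segmentation error structure, contouring drift between observers,
schedule interruptions, or model misspecification — on synthetic data the
fitted model is the generating model. Passing calibration and coverage
tests on synthetic cohorts therefore demonstrates internal statistical
correctness, not clinical transportability.

## Problem sizes used by the test suite

The shipped tests exercise the full pipeline at reduced sizes chosen to
keep the statistical checks sharp while remaining quick to run: MCMC at
1–30 thousand iterations over 2–4 chains depending on the check,
training cohorts of 4–10 synthetic patients, second-level priors of
2,500–20,000 particles, 50-replicate coverage experiments, and
prior-predictive classification at 20,000–100,000 draws. The acceptance
script uses 100,000 prior draws. Production-scale defaults (4 × 25,000
MCMC iterations, 100,000-particle second-level prior) are the package
defaults in `rt_config()`.

## Known limitations

* The pooled posterior is only as representative as the training cohort;
  rare classes (plateaued, pseudo-progression) carry little prior mass
  and are identified late, if at all, from GTV alone.
* Per-fraction response is dose-agnostic (`gamma` per fraction; recorded
  Gy are metadata), appropriate while all fractions are 2 Gy.
* Noise parameters are global; per-patient noise would confound the
  static-parameter particle filter.
* The bootstrap filter reweights a fixed particle set; with highly
  informative records the effective sample size can become small, and
  the ESS diagnostic should be checked before trusting narrow bands.
* Classification of noisy clinical series is indirect: class
  probabilities come from classified posterior particles, never from
  thresholding noisy data directly.
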