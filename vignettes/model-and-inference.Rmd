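---
title: "Model and inference in abfew"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and inference in abfew}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`abfew` predicts quantitative amyloid-beta (Abeta) accumulation in
wild-type (WT) and Alzheimer's-model (AD) animals from behavioural
biomarker measurements, in the common experimental situation where most
animals have *either* an Abeta measurement *or* a biomarker vector, and
only a small subset has both. This vignette documents the model, its
assumptions, the inference machinery, the synthetic-cohort generator,
and the numerical and design decisions baked into the implementation.

## The generative model

### Accumulation curves

Each animal $i$ carries logistic-accumulation parameters
$\theta_i = (\alpha_i, \beta_i, \gamma_i)$. Its Abeta level at age $t$
(months) is

$$ z_i(t) = \alpha_i \, \sigma(\beta_i t - \gamma_i), \qquad
   \sigma(u) = \frac{1}{1 + e^{-u}}, $$

so $\alpha_i$ is the saturation level, $\beta_i$ the accumulation rate,
and $\tau_i = \gamma_i / \beta_i$ the age at which accumulation reaches
half its saturation — the curve's inflection point, where the speed

$$ z_i'(t) = \beta_i \, z_i(t)\left(1 - z_i(t)/\alpha_i\right) $$

peaks at $\alpha_i \beta_i / 4$. Observed Abeta is
$y_i \sim \mathcal N(z_i(t_i), \sigma_y^2)$ with $\sigma_y$ fixed at
$0.05$ (levels are analysed on a scale normalized so that typical AD
saturation is near 1).

### Type hierarchy

Animals belong to a type $k \in \{\mathrm{WT}, \mathrm{AD}\}$.
Per-animal parameters are exchangeable within type:

* $\alpha_i, \beta_i \sim \mathcal N_+(\mu_{\varphi,k},
  \sigma^2_{\varphi,k})$, normal truncated to $(0, \infty)$ — both must
  be positive for the curve to be an accumulation;
* $\gamma_i \sim \mathcal N(\mu_{\gamma,k}, \sigma^2_{\gamma,k})$,
  untruncated.

Hyper-priors are conjugate-style: $\mu_{\varphi,k} \sim \mathcal
N(m_\varphi, v_\varphi^2)$ and $\sigma^{-2}_{\varphi,k} \sim
\mathrm{Gamma}(a_\varphi, b_\varphi)$ with the fixed constants
$v = (0.1, 0.1, 1)$, $a = (25, 100, 10)$, $b = (0.5, 1, 1)$ for
$(\alpha, \beta, \gamma)$ (see `prior_config()`).

### Emission of biomarkers

A biomarker vector $x_i \in \mathbb R^L$ is a noisy linear readout of
the latent accumulation *state*: the level, its speed, and an
intercept,

$$ g(\theta_i, t_i) = \big(z_i(t_i),\; C\,z_i'(t_i),\; 1\big), \qquad
   x_{il} \sim \mathcal N\!\big(w_l^\top g(\theta_i, t_i),\,
   \sigma^2_{x,l}\big). $$

$C$ rescales the speed so its prior-typical peak is order 1; the
default is $C = 4 / (\mu_{\beta,\mathrm{AD}}\,\mu_{\alpha,\mathrm{AD}})$
evaluated at the step-1 posterior means. Weight rows have independent
priors $w_{ld} \sim \mathcal N(0, \sigma^2_{w,l})$, and the precisions
carry Gamma priors with $a_w = 100$, $b_w = 1000$ (weights) and
$a_x = 0.5$, $b_x = 1$ (feature noise). A two-component variant without
the speed term is available via `include_derivative = FALSE`.

### Assumptions worth stating

* Accumulation is monotone logistic; no regression or non-sigmoidal
  dynamics.
* Biomarkers depend on age *only through* the latent state
  $(z, z')$ — the intercept column absorbs feature-specific offsets,
  but there is no direct age effect.
* Feature noise is Gaussian, homoscedastic per feature, independent
  across features given the latent state.
* Each animal is observed once (cross-sectional design); per-animal
  curves are identified only through the hierarchy.
* WT and AD differ only through the hierarchy parameters, not the
  emission weights.

## Two-step learning

Paired samples are too few to fit everything jointly from scratch, so
learning is split:

**Step 1** (`step1_pretrain()`) uses only Abeta-observed samples. Each
sample contributes its likelihood plus a pseudo-observation $y = 0$ at
$t = 0$ (curves must start near zero). A nonlinear least-squares pass
(`least_squares_init()`, via `minpack.lm`) initializes per-type curves;
MCMC then samples per-animal parameters and the hierarchy.
`summarize_hyperposterior()` compresses the hyper-posterior by moment
matching — Gaussian for each $\mu_{\varphi,k}$, Gamma (shape
$= \text{mean}^2/\text{var}$, rate $= \text{mean}/\text{var}$) for each
precision — into the object that becomes step 2's prior.

**Step 2** (`step2_train()`) uses biomarker-observed samples, including
the paired ones (whose $y$ enters the likelihood directly). Each sweep:

* weight rows $w_l$ — exact conjugate draw from the full multivariate
  normal conditional with precision
  $\Lambda_l = Z^\top Z / \sigma^2_{x,l} + I / \sigma^2_{w,l}$
  (`gibbs_update_weights()`);
* noise and weight-scale precisions — exact conjugate Gamma draws
  (`gibbs_update_variances()`); the noise-precision shape is
  $a_x + N/2$ (a `compat_printed_shape` flag exposes an alternative
  $a_x + 2/N$ form for auditing);
* per-animal $\theta_i$, the type means $\mu_{\varphi,k}$, and the
  log-precisions — adaptive random-walk Metropolis.

### Sampler design

The non-conjugate block uses random-walk Metropolis with Robbins–Monro
scale adaptation (rate $i^{-0.6}$, burn-in only, so the kept chain is a
valid time-homogeneous Markov chain). $\alpha$ and $\beta$ are sampled
on the log scale (with the Jacobian in the acceptance ratio) to respect
positivity; precisions as $\eta = \log \lambda$. Two extra moves fix
well-known pathologies of centered hierarchies:

* a **group-shift move** that translates a type mean
  $\mu_{\varphi,k}$ *together with* all that type's per-animal
  parameters, curing the slow random walk that per-coordinate updates
  exhibit along the hierarchy's "funnel";
* a **ridge move** that shifts $(\beta, \gamma)$ jointly along a fixed
  direction preserving the half-saturation age $\tau = \gamma/\beta$,
  which the data identify much more sharply than $\beta$ and $\gamma$
  separately.

Convergence is monitored with split-$\hat R$ and an
initial-sequence-estimator effective sample size on the hierarchy
parameters and weights; `step2_train()` warns when any monitored
$\hat R$ exceeds `rhat_warn`.

## Prediction

`predict_abeta()` forms the posterior predictive for a new biomarker
vector $x_\star$ as a mixture over posterior draws, candidate ages on a
grid (default 2–18 months), types, and per-draw auxiliary parameter
draws from the hierarchy. Component weights are proportional to the
Gaussian likelihood of $x_\star$ under each component's emission means,
computed in log space and normalized by log-sum-exp. The reported
point estimate is the weighted mean (or median), the interval a
weighted quantile interval, and the type posterior the per-type weight
sum — so $P(\mathrm{WT}) + P(\mathrm{AD}) = 1$ by construction.

## The synthetic-cohort generator

`generate_synthetic_study()` simulates cohorts with known ground truth;
its defaults *are* the study conditions used by the test suite and the
`scripts/acceptance.R` run:

* AD hierarchy means $(\alpha, \beta, \gamma) = (1.0, 0.45, 4.5)$ with
  sds $(0.10, 0.05, 0.5)$; WT $\alpha$ mean $0.01$ (sd $0.003$) with
  the same $\beta, \gamma$ — WT animals accumulate essentially nothing;
* feature noise $\sigma_x = 0.5$, Abeta noise $\sigma_y = 0.05$;
* true weight rows drawn $\mathcal N(0, 1.5^2)$, redrawn until the
  larger of the level/speed loadings exceeds $0.5$, so every feature
  carries signal;
* the default design: per type, 20 Abeta-only, 50 biomarker-only and
  50 paired animals, ages sampled from $\{4, 6, \dots, 16\}$ months,
  $L = 11$ features.

What the generator does **not** emulate: longitudinal repeated
measures, floor/ceiling or assay-saturation effects, non-Gaussian or
heteroscedastic noise, age-dependent missingness, features that depend
on age directly, batch effects, or any WT/AD difference in the
emission. `generate_fixture_study()` mimics a realistic unbalanced
composition (AD-only Abeta observations, no paired WT) for exercising
the preprocessing path — `augment_virtual_wt()` adds zero-level virtual
WT samples so step 1 can see both types.

## Numerical choices

* Truncated-normal densities and draws are computed in log space with
  `pnorm(..., log.p = TRUE)` so deep-tail normalizations do not
  underflow; deep-tail sampling falls back to inversion.
* Mixture weights and type posteriors use log-sum-exp throughout.
* Conjugate weight draws solve the precision system by Cholesky rather
  than inverting $\Lambda_l$.
* All CSV output (`write_samples_table()`, `write_fit()`) prints
  numerics with `%.17g` — round-trip exact for doubles — which is what
  makes CLI reruns byte-identical.
* Moment-matched Gamma summaries floor the sd at a small positive
  value to avoid degenerate (infinite-precision) step-2 priors.

## Decisions on underdetermined points

Several details admit more than one reading; the implementation commits
to the following, chosen for leakage control and auditability:

* **Cross-validation holds out both $x$ and $y$** of a held-out paired
  sample ("strict" mode). A "lenient" mode that keeps the held-out
  $x$ in training as unpaired data is available for comparison.
* **Step 1 is not refit per fold**: it touches no biomarker data, so
  held-out features cannot leak through it.
* **Presence/absence calls** threshold the predicted level at
  $\varepsilon = 0.05$ (the Abeta noise sd), since posterior means are
  never exactly zero.
* **Noise-precision shape** uses the conjugate $a_x + N/2$; the
  alternative printed form is available behind `compat_printed_shape`.
* $\sigma_y$ is fixed, not learned.

## Limitations

* Per-animal parameters for *Abeta-only* samples are integrated out of
  step 2 via the moment-matched summary rather than carried jointly;
  the summary is an approximation to the exact hyper-posterior.
* The tight empirical-Bayes hyper-priors concentrate the type means
  quickly; with few or noisy Abeta samples the type-mean intervals can
  be overconfident along weakly identified directions (notably the
  $(\alpha)$ scale and the $(\beta, \gamma)$ ridge), even when
  per-animal intervals are well calibrated.
* Reduced MCMC settings used in evaluation loops (e.g. 500 + 500
  draws) trade some convergence quality for runtime; `step2_train()`
  defaults are 10× larger and diagnostics are always attached.
* Cross-sectional data cannot distinguish an animal's fast
  accumulation from an early onset except through the hierarchy.

## A minimal session

```{r, eval = FALSE}
library(abfew)
study <- generate_synthetic_study(cohort_design(), truth_config(),
                                  seed = 42)
pre <- step1_pretrain(study$dataset,
                      mcmc = mcmc_config(3, 3000, 3000, seed = 1))
fit <- step2_train(study$dataset, pre$summary,
                   mcmc = mcmc_config(3, 500, 500, seed = 2))
i <- study$dataset$S_XY[1]
predict_abeta(study$dataset$X[i, ], fit, max_draws = 300, seed = 1)
cv <- cross_validate(study$dataset, pre$summary, scheme = 4,
                     mcmc = mcmc_config(3, 500, 500, seed = 5),
                     seed = 5)
```

The README shows this session with its actual printed output, and the
same pipeline is scripted end to end in `scripts/acceptance.R`.
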