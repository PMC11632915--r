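---
title: "Empirical carbon-ion RBE modelling with cirbe: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Empirical carbon-ion RBE modelling with cirbe: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cirbe)
```

## The model

Clonogenic survival after a dose $D$ of radiation is described throughout by
the linear-quadratic model (LQM),

$$\mathrm{SF}(D) = \exp(-\alpha D - \beta D^2),$$

with $\alpha$ [Gy$^{-1}$] and $\beta$ [Gy$^{-2}$] specific to the cell line
and radiation quality. Carbon-ion beams kill more efficiently than the
photon reference, and the ratio of iso-effective doses — the relative
biological effectiveness (RBE) — varies strongly with the beam's
dose-weighted linear energy transfer (LET$_d$) and with the dose level, so
treatment planning needs a model of $(\alpha_C, \beta_C)$ as a function of
the photon reference response $(\alpha_X, \beta_X)$ and LET$_d$.

`cirbe` implements an empirical model built on one robust observation:
radiosensitivity *endpoints* — the dose $D_{\mathrm{SF}}$ achieving a given
surviving fraction — are linearly correlated between photon and carbon-ion
irradiation across cell lines, with a slope that decays with LET$_d$ and an
intercept that grows slowly with it. Working with the two endpoints at
survival levels $e^{-3}$ ($\approx 5\%$) and $e^{-1}$ ($\approx 37\%$),
the model maps photon endpoints to carbon-ion endpoints as

$$D_{e^{-3}\!,C} = D_{e^{-3}\!,X}\,(1 + f_1\,\mathrm{LET}_d)^{-1}
   + q_1\,\mathrm{LET}_d^2 + m_1, \qquad
  D_{e^{-1}\!,C} = D_{e^{-1}\!,X}\,(1 + f_2\,\mathrm{LET}_d)^{-1},$$

four constants in all: $f_1, f_2$ [(keV/µm)$^{-1}$], $m_1$ [Gy], $q_1$
[(keV/µm)$^{-2}$, dose-scaled]. Units are fixed package-wide as Gy and
keV µm$^{-1}$; there is no unit-conversion layer.

Because the two survival levels are powers of $e$, the log-survival values
at the two endpoints are exactly 3 and 1, and the LQM coefficients
interpolating both endpoints have closed forms

$$\alpha_C = \frac{D_3^2 - 3 D_1^2}{D_1 D_3^2 - D_3 D_1^2}, \qquad
  \beta_C  = \frac{3 D_1 - D_3}{D_1 D_3^2 - D_3 D_1^2},$$

writing $D_3 = D_{e^{-3}\!,C}$, $D_1 = D_{e^{-1}\!,C}$. Negative
coefficients are geometrically possible ($\beta_C < 0$ iff $D_3 > 3 D_1$,
$\alpha_C < 0$ iff $D_3 < \sqrt3\, D_1$; the two conditions are mutually
exclusive) and are resolved by zeroing the offending coefficient and
least-squares-fitting the other alone through the endpoint lethalities
$(3, 1)$:

$$\alpha_{C(\beta=0)} = \frac{3 D_3 + D_1}{D_3^2 + D_1^2}, \qquad
  \beta_{C(\alpha=0)} = \frac{3 D_3^2 + D_1^2}{D_3^4 + D_1^4}.$$

Every prediction records which branch it took (`unconstrained`,
`beta_zeroed`, `alpha_zeroed`). The `beta_zeroed` branch is reached by
*every* positive-$\beta_X$ input above some finite LET — the quadratic
intercept keeps $D_3$ from shrinking while $D_1$ decays — which is how the
model reproduces the linearization of survival curves
($\alpha_C/\beta_C \to \infty$) seen at high LET, and, together with the
slope decay, the overkill maximum in RBE$_{10}$ versus LET.

```{r example}
photon <- lqm(0.3, 0.03)
pred <- predict_cion_lqm(photon, let_d = 60.5)
pred
rbe_at_survival(photon, pred$lqm, 0.10)
```

The packaged constants (`published_parameters()`) are the published values
fitted to a curated compilation of 360 cell-line/LET survival records,
together with their full 4×4 covariance.

## Conventions and numerical choices

**RBE at a dose level.** "RBE at 2 Gy" is ambiguous: the stated dose can be
the ion dose or the photon dose. `rbe_at_dose()` fixes the *carbon-ion*
dose by default (the iso-effect convention usual for ion-beam survival
comparisons): the survival produced by the ion dose is computed and the
photon dose achieving that survival is divided by the ion dose. The
photon-dose-fixed variant is available via `fixed = "photon"`. All
validation metrics use the default convention.

**Dose inversion.** $D(\mathrm{SF})$ solves a quadratic; the textbook root
$(-\alpha + \sqrt{\alpha^2 + 4\beta L})/(2\beta)$, $L = -\ln \mathrm{SF}$,
loses up to five digits to cancellation whenever
$\beta \lesssim 10^{-6}\alpha^2$. The package uses the algebraically
equivalent, cancellation-free form $D = 2L/(\alpha + \sqrt{\alpha^2 +
4\beta L})$, which degrades gracefully to $L/\alpha$ at $\beta = 0$ and to
$\sqrt{L/\beta}$ at $\alpha = 0$ and keeps the round trip through
`survival_fraction()` below $10^{-10}$ relative everywhere.

**Endpoint ordering.** Predicted endpoints must satisfy $D_3 > D_1 > 0$;
violations (possible only for pathological parameter values) raise an
error at prediction time and a finite objective penalty during fitting,
rather than being silently clamped.

**Non-negativity of inputs.** Photon inputs with $\beta_X < 0$ are
rejected, mirroring the training-data curation rule; $\alpha_X = 0$ with
$\beta_X > 0$ is accepted.

## Training machinery

**Distance metric.** Fitting minimizes, over records, the squared
normalized curve distance

$$L2_{0.5\text{–}4\,\mathrm{Gy}} =
  \frac{\sqrt{\int_{0.5}^{4} (\mathrm{SF}_m - \mathrm{SF}_p)^2\,dD}}
       {\int_{0.5}^{4} \mathrm{SF}_p\,dD},$$

restricted to 0.5–4 Gy so that the low-dose shoulder — where biological
uncertainty is largest — does not dominate. The integrals use composite
Simpson quadrature on a fixed 513-point grid by default; a test asserts
agreement with a 10× finer grid below $10^{-6}$ for LQM curves, and the
grid size is a configuration knob (`fit_config(grid_n = )`).

**Trend selection.** For each endpoint, candidate slope and intercept
families (an extensible registry shipping the inverse-linear slope, its
square, the quadratic-offset intercept, and the zero intercept) are fitted
by least squares on *relative* endpoint residuals
$(D_{\mathrm{pred}} - D_{\mathrm{meas}})/D_{\mathrm{meas}}$ and compared by
BIC, $n\ln(\mathrm{RSS}/n) + k\ln n$. BIC's stronger parameter penalty is
deliberate at this stage: each endpoint's description should stay minimal
before several endpoints are composed into one model.

**Endpoint-combination selection.** `select_endpoint_combination()` scores
every 2-, 3- and 4-endpoint combination of
$\{e^{-3}, e^{-2}, e^{-1}, e^{-1/2}\}$: per-record, the trend-predicted
endpoints are converted to an LQM curve by (possibly constrained) least
squares over the endpoint set, the summed squared $L2$ distances give the
RSS, and combinations are ranked by
$\mathrm{AICc} = n\ln(\mathrm{RSS}/n) + 2k + 2k(k+1)/(n-k-1)$. Additive
likelihood constants are dropped in both criteria, so only differences are
meaningful and printed AICc values from other software are not
comparable.

**Global fit.** `fit_model()` minimizes the sum of squared $L2$ distances
over $(f_1, m_1, q_1, f_2)$ with non-negativity bounds. The objective is
start-sensitive (distinct local minima are observed on noisy data), so the
fit is multi-start: per-endpoint trend fits give a base point and
`n_starts` initial guesses are drawn within ±10% of it (default 10 000, as
in the published procedure; tests and the bundled experiments use ≤100).
Each start is polished by the bounded PORT quasi-Newton optimizer
(`stats::nlminb`) with an analytic objective gradient — derived by chaining
the branch-specific endpoint-to-LQM derivatives through the quadrature —
which is verified against central finite differences in the test suite.
The bounded L-BFGS-B optimizer was tried first and rejected: its internal
finite-difference gradient requires the objective to be finite everywhere,
and the infeasible endpoint-ordering region is handled here by a large
finite penalty that PORT backs out of robustly. Fits are deterministic
given the configured seed and invariant to record order.

**Parameter covariance.** The reported 4×4 covariance is the Gauss–Newton
approximation $\hat\sigma^2 (J^\top J)^{-1}$ on the per-record $L2$
residuals, $\hat\sigma^2 = \mathrm{RSS}/(n-4)$. How the published
covariance was obtained is not documented; Gauss–Newton is this package's
choice, and a simulation test checks that its off-diagonal signs agree
with refit scatter.

## Uncertainty propagation

Confidence bands are propagated on the $\ln \mathrm{SF}$ scale (which
guarantees positive bands after exponentiation) and use the coverage
factor 1.96 for 95% bands and 1.0 for 68.3% bands, exactly.

For *measured* curves the delta method is exact:
$\mathrm{var}(\ln \mathrm{SF}) = D^2\mathrm{var}(\alpha) +
D^4\mathrm{var}(\beta) + 2D^3\mathrm{cov}(\alpha,\beta)$.

For *predicted* curves the gradient of $\ln \mathrm{SF}(D)$ with respect to
the four constants is taken by central finite differences (relative step
$10^{-5}$) through the prediction chain with the constraint branch held
fixed at the central prediction's branch; the branch switch is a
measure-zero non-smoothness, and a warning is issued when a perturbation
would cross it.

**Known limitation.** With the published covariance the delta method is
only locally valid: $f_1$ carries a ~41% relative standard error, and
$(1+f_1\mathrm{LET})^{-1}$ is strongly convex over that spread once
$f_1\,\mathrm{LET} \sim 1$. Monte-Carlo sampling of the parameter
distribution therefore spreads ~2% wider than the delta band at LET 13.5
but ~19% wider at LET 60.5 (the discrepancy is dose-independent on the
`beta_zeroed` branch, where $\ln\mathrm{SF}$ is linear in $\alpha_C$).
Scaling the covariance down by $10^{-2}$ brings agreement below 0.5%,
confirming the gap is curvature, not implementation. Delta bands at mid
LET should be read as slight underestimates; the acceptance suite records
this as a failing 5%-concordance check rather than hiding it.

## Validation

`loocv()` refits the model with each record held out (reduced multi-start
budget, default 50 starts — full retraining per refit is the procedure;
the budget is a tractability choice) and predicts the held-out record;
a content hash of each training subset enforces that no refit saw its
target. `rbe_deviations()` evaluates relative RBE deviations at the 0.5,
1, 2 and 4 Gy carbon-ion dose levels; `bootstrap_intervals()` resamples
them *within each dose level* (the alternative — jointly across levels —
is not what the per-dose-level prediction intervals describe) and reports
mean percentile endpoints over 2000 resamples; `let_bin_summary()` groups
deviations into the clinical SOBP regions
$[0,20), [20,40), [40,70), [70,100), [100,200), [200,\infty)$ keV µm$^{-1}$,
left-closed so the region inequalities are exact;
`comparison_metrics()` reports mean absolute relative deviations for
$D_{10\%}$, $D_{50\%}$ and RBE at 1, 2, 4 Gy with standard errors, fed by
held-out predictions to measure predictive rather than descriptive
accuracy.

## The synthetic world

The generator (`generate_synthetic_dataset()`) emulates the *structure* of
curated survival compilations, not any particular dataset: by default 8
cell lines at LET$_d \in \{13.5, 27.9, 60.5\}$ keV µm$^{-1}$ (the design
of the experimental series the correlation analysis was built on), photon
parameters drawn uniformly from $\alpha_X \in [0.05, 0.8]$ Gy$^{-1}$ and
$\beta_X \in [0.005, 0.1]$ Gy$^{-2}$ (spanning roughly $D_{10\%,X}$ from
1.4 to 8.6 Gy, the sensitivity spread of that series), a 6 MV reference
source recorded as 6000 kVp-equivalent (megavoltage sources are stored as
1000×MV so the "< 200 kVp" curation rule is one numeric threshold), and
carbon-ion responses generated from a known ground-truth parameter set
(default: the published constants).

Noise is applied *to the endpoints* — each true endpoint is multiplied by
an independent unit-mean lognormal factor with configurable CV (5% where a
noisy world is needed) — because the model's error structure is defined on
endpoint space. Draws violating $D_3 > D_1$ are resampled rather than
clamped (clamping would distort the noise distribution); the noisy
endpoints then pass through the constrained conversion, so generated
records always satisfy the post-filter invariants ($\beta_C \ge 0$).

What a green test on this world does establish: the estimator recovers the
constants that generated the data, the selection machinery identifies the
generating endpoint pair, and held-out predictions are unbiased at the
injected noise scale. What it does not establish: performance on real
survival compilations, whose noise is neither lognormal nor independent
across endpoints, whose LET and cell-line coverage is uneven, and whose
photon references vary in quality — none of which the generator emulates.

## Reproducibility

Every stochastic routine takes an explicit seed and restores the caller's
RNG state; fits are invariant to record order; the CLI
(`run_cli()`, with the launcher installed at `inst/cli/cirbe`) writes a
provenance sidecar (configuration echo and hash, package version,
parameter-resource version) next to every output and refuses to overwrite
without `--force`.
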