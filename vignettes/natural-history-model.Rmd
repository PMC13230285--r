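---
title: "Joint natural-history modelling of DCIS and invasive breast cancer"
author: "dcisnat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint natural-history modelling of DCIS and invasive breast cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcisnat)
```

## The model

`dcisnat` models the occult progression of breast cancer through five
states: healthy, preclinical DCIS (ductal carcinoma in situ), symptomatic
DCIS, preclinical invasive cancer, and symptomatic invasive cancer.  The
population is assumed *stable*: onset and transition rates do not depend on
calendar time, so the joint distribution of everything observable at a
screening round or in a window of symptomatic diagnoses is stationary.

Each lesion carries an individual inverse growth rate $R \sim
\Gamma(\tau_1, \tau_2)$ (shape/rate; years per $e$-fold of invasive tumour
volume), shared between the in-situ and invasive phases of the same
individual.  Given $R = r$:

* the DCIS lesion diameter follows the power law
  $l_r(t) = \left(k t (1-\beta)/r + l_0^{1-\beta}\right)^{1/(1-\beta)}$
  from a fixed initial diameter $l_0 = 0.03$ mm ($\beta < 1$; negative
  values give fast early growth);
* the invasive tumour volume grows exponentially,
  $V_r(t) = v_0 e^{t/r}$, from a fixed $v_0 = 0.05\ \mathrm{mm}^3$
  (diameters assume spherical tumours, $v = (\pi/6) d^3$);
* exit from the preclinical DCIS state is a competing risk between
  symptomatic detection and transition to invasiveness, both with hazards
  proportional to current lesion size:
  $h_{T_D}(t\mid r) = \eta_D\, l_r(t)$, $h_{T_T}(t\mid r) = \eta_T\,
  l_r(t)$;
* symptomatic detection of invasive cancer has hazard proportional to
  current volume, $h_{T_I}(t\mid r) = \eta_I V_r(t)$;
* an attended mammography screen detects a preclinical DCIS lesion with
  probability $\operatorname{logit}^{-1}(b_0 + b_1 l)$ and a preclinical
  invasive tumour with probability
  $\operatorname{logit}^{-1}(b_0 + b_1 l + b_2 d)$ — the in-situ component
  keeps growing after transition and contributes to invasive detection.

Because the exit hazards from the DCIS state are proportional, the
probability of exiting via symptoms is the constant $a = c/(1+c)$ with
$c = \eta_D/\eta_T$, for any growth law and any $r$.

Three consequences of stationarity drive everything else: membership of a
preclinical state at a calendar instant is length-biased by the sojourn
time; the time already spent in a state is uniform given the sojourn; and
the expected numbers of preclinical DCIS and invasive cancers per unit
onset rate are $E(T_e)$ and $(1-a)E(T_I)$, with $T_e = \min(T_D, T_T)$.
This yields closed forms (through the Laplace transform
$F(s) = (\tau_2/(\tau_2+s))^{\tau_1+1}$ of the shifted Gamma prior) for the
symptomatic size densities, the stationary preclinical size densities, and
the membership probability
$E(T_e) / \{E(T_e) + (1-a)E(T_I)\}$, which the default parameters put at
0.4078.

## Default parameters

The defaults of `nh_params()` are the reference simulation-study
configuration: $\beta = -0.8$, $k = 15$ (mm$^{1-\beta}$/y),
$\tau_1 = 2.36$, $\tau_2 = 3$ (median inverse growth rate 0.68 y),
$\ln\eta_T = -4.5$, $\ln\eta_D = -6.5$ (so $c = e^{-2}$ and
$a \approx 0.119$: about 88% of untreated lesions would transition),
$\ln\eta_I = -8.75$, and sensitivities $b_0 = -5$, $b_1 = 0.1$/mm,
$b_2 = 0.56$/mm.  $l_0$ and $v_0$ are fixed constants of the growth laws
and are never estimated.

```{r membership}
p <- nh_params()
membership_summary(p)
```

## The synthetic-data generator

`simulate_population()` reproduces the study design that the theory
describes: a fixed number of onsets at every 0.01-year calendar step (the
reference full scale is 2000 per step over calendar years 0–400, i.e.
2·10^5 onsets/year), inverse growth rates from the Gamma prior, sojourn
times by exact closed-form inversion of the cumulative hazards, and an
optional biennial screening programme (calendar years 300–340) in which
every individual attends every offered screen.  Case datasets are drawn
with `sample_case_dataset()`: a Bernoulli 14% sample of the final
screening round and of two years of symptomatic diagnoses, each record
carrying type, mode, size (mm) and all attended screen times.

What the generator deliberately does *not* emulate: birth/death
demography, non-attendance, calendar trends in any rate, measurement error
in recorded sizes, and de-novo invasive cancers (the piecewise early
transition hazard `de_novo_config()` is provided and tested but off by
default and excluded from estimation).  Passing tests therefore show
internal consistency of theory, simulator and likelihood under the model's
own assumptions — not that the model describes any real screening
programme.

Two implementation choices matter for large runs.  Only onsets within a
*sojourn horizon* of the window of interest are materialised: the horizon
is chosen at run time so that the expected number of individuals older
than it that would still be undetected is below 0.1 (about 95 years at
the defaults), which makes the full-scale snapshot feasible in a few
hundred MB.  Onset cohorts are generated in fixed chunks of calendar
steps with per-chunk seeds derived from the root seed, so results depend
only on the seed (and the fixed chunk layout), not on available memory.
A screen falling at the exact instant of transition uses the invasive
sensitivity; one at the exact instant of onset sees a lesion of size
$l_0$.

## The incident-cases likelihood

For a case detected at calendar time $s$, the conditional likelihood of
(type, size) given the detection mode and the attended-screen history
marginalises the latent $(r, t_t)$: back-projection reconstructs the
lesion and tumour sizes at every earlier screen from the size at
detection, with sensitivity zero before onset, the DCIS sensitivity
between onset and transition and the invasive sensitivity after.  The
four class contributions and the class normalization constants (the sum
of the invasive-size and DCIS-size integrals of the unnormalised
contributions, one constant per screening pattern and class) follow the
stationary theory; the unknown onset-rate-to-population-size constant
cancels and is never exposed.

Numerical design:

* growth-rate integrals use generalized Gauss–Laguerre rules matched to
  the Gamma prior; the joint survival factor
  $e^{-(\eta_D+\eta_T) r \Phi(l)}$ (DCIS classes) or
  $e^{-\eta_I r (v - v_0)}$ (invasive classes) is absorbed into the
  measure by scaling the rule per size point, which makes the
  empty-history contributions exact to machine precision at any order and
  keeps the rules accurate arbitrarily far into the size tails;
* transition-time integrals use the exact probability-integral transform
  of the exit time $T_e$ given $r$ (closed-form quantiles), absorbing the
  $S_{T_D}$ factor with no domain truncation;
* normalizer size integrals use importance nodes from the closed-form
  symptomatic-size quantiles (symptomatic classes) or numeric quantiles
  of the length-biased stationary densities in log-size coordinates
  (screen classes, whose integrands spike at the size floor);
* when all symptomatic cases share one screening pattern up to a calendar
  shift (the biennial design), their normalization constants are
  evaluated at Chebyshev nodes of the shift and spline-interpolated —
  accurate to a few parts in 10^3 in the log constant, commensurate with
  the quadrature accuracy at fitting orders, and validated against exact
  per-pattern evaluation in the tests;
* the hot loops (quadrature nodes × attended screens) are implemented in
  C++.

Default orders are 64 (`quad_settings()`); fits use lighter settings
(see below).  The screen-detected invasive contribution is implemented in
two algebraically equivalent arrangements (survival-function form and
conditional-density form of the sojourn kernel); they agree to 1e-6 on
smooth (empty-history) integrands and to quadrature accuracy (~2e-3 at
order 64) when long screening histories introduce kinks in the
growth-rate integrand.

## Estimation

`fit_model()` maximises the conditional log-likelihood over up to ten
parameters in unconstrained coordinates ($\log$ for positive parameters,
$\log(1-\beta)$ for the exponent, identity for $b_0, b_1, b_2$).  The
growth coefficient $k$ is fixed by default: $(k, \beta)$ are only weakly
jointly identified and many pairs give near-identical growth curves.

The transformed likelihood surface is a narrow curved valley with strong
correlations among $(\tau_1, \tau_2)$, the hazard coefficients and the
sensitivity slopes.  Generic quasi-Newton updates (L-BFGS-B with
finite-difference gradients) stall far from the optimum on this valley —
from their stopping points the log-likelihood still ascends monotonically
towards the optimum — so the default optimiser is Fisher scoring: per-case
score vectors by central differences, the outer-product (BHHH)
approximation to the information matrix, and a step-halving line search
clamped to box bounds.  This reaches optimum-level log-likelihoods
reliably in 15–30 iterations.  L-BFGS-B remains available as
`method = "l-bfgs-b"`.

Two safeguards matter.  First, wide but biologically motivated default
bounds (e.g. $\tau_2 \ge 0.3$, $\eta_I \le 0.01$, $b_0 \in [-12, 0]$,
$b_1, b_2 \ge 0$: sensitivity non-decreasing in size, baseline detection
below one half) keep the optimiser out of degenerate corners where the
model density collapses to spikes and coarse quadrature over-estimates the
likelihood — without bounds an aggressive optimiser can manufacture
arbitrarily large fake likelihood gains there.  Second, fits use moderate
quadrature orders (12–16) for speed; the quadrature error is smooth in the
parameters and orders of magnitude below the statistical information at
the recommended sample sizes.

## Problem sizes and what the recovery study shows

The package's estimation study mirrors the reference design (biennial
screening 300–340, 14% sampling) at one twentieth of the reference onset
rate — about 2,800 cases per dataset, chosen so that ten simulate-and-fit
replicates complete in minutes.  At that size the fits reach the maximum
of the likelihood, but the sampling noise in the weakly identified
directions (notably the median growth rate) leaves the recovered
screening-sensitivity curve with typical maximum relative errors around
1–2 and the transition-hazard curve around 0.3–1.  These errors scale as
$1/\sqrt{n}$: at the reference design's full sample size (about 5.5·10^4
cases) they extrapolate to roughly 0.2, which is what the tight recovery
bands published for this design reflect.  The package's acceptance test
asserts the 50% band at the feasible scale and is expected to fail there;
the per-replicate errors it computes are the honest summary of what the
scaled-down study can show.

## Known limitations

* Proportional exit hazards are baked into the closed forms and the
  samplers; the likelihood evaluators use the proportional-hazards
  quantile transforms, so non-proportional exit models would need new
  node schemes (the contribution structure itself is general).
* The invasive sensitivity uses the ever-growing in-situ component; if
  lesions stop growing at transition, screen-detected invasive counts
  drop and the 80/20 detection-mode split shifts.
* All screens are attended; the record structure carries attended screens
  only.
* Standard errors from the scoring information matrix are not reported;
  the recovery diagnostics are curve-based.
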