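---
title: "Modelling tumour spheroid growth and adaptation to changing oxygen"
author: "spheroidadapt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling tumour spheroid growth and adaptation to changing oxygen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spheroidadapt)
```

## The biological system and the model

Avascular tumour spheroids grown in vitro pass through three phases:
(i) exponential growth with proliferation throughout; (ii) growth with a
central shell of living but arrested cells (the *inhibited* region, radius
$R_i$); and (iii) saturating growth with a central *necrotic* core (radius
$R_n$) inside the inhibited shell, all inside the outer radius $R_o$.
This package implements a quasi-steady reaction–diffusion description of
the internal oxygen and metabolic-waste fields, the classical
volume-conservation growth law coupling them, and two switching extensions
describing adaptation when the ambient oxygen changes abruptly
(deoxygenation: normoxia $\to$ hypoxia; re-oxygenation: hypoxia $\to$
normoxia), together with the statistical machinery to calibrate all of
them to per-spheroid radial measurements.

### Internal fields

Oxygen diffuses quickly relative to growth, so its partial pressure
$p(r)$ solves a steady diffusion–consumption balance in a sphere whose
core (where $p$ has hit the necrotic threshold $p_n = 0$) does not
consume. The closed form on $R_n \le r \le R_o$ is

$$p(r) = \max\!\left(0,\; p_\infty - a\left[R_o^2 - r^2
  - 2R_n^3\!\left(\tfrac1r - \tfrac1{R_o}\right)\right]\right),$$

with $p \equiv 0$ inside the core. The single lumped coefficient
$a = \Omega\alpha/(6k)$ (pressure per squared length) is all the dynamics
ever need; the SI constants — diffusivity $k$, consumption rate $\alpha$,
conversion constant $\Omega$ — enter only through the explicit conversion
helpers (`critical_radius_from_constants()`, `alpha_from_critical_radius()`)
and are configurable in `oxygen_constants()`, never hard-coded. The
**critical radius** $R_c = \sqrt{p_\infty / a}$ is the outer radius at
which the centre first becomes anoxic and a core forms.

Metabolic waste is produced by living cells and diffuses out; with a zero
surface concentration its profile is the mirror image
$\beta(r) = b\,[R_o^2 - r^2 - 2R_n^3(1/r - 1/R_o)]$ with $b = P/(6\kappa)$.
The zero-surface boundary condition is a modelling choice made here
because it makes the inhibited-radius constraint below exactly the
$r = R_i$ evaluation of this profile; it is the natural open-bath
idealisation for a well-mixed medium.

### Structure constraints and growth law

Evaluating the fields at their thresholds gives two algebraic constraints
that, given $R_o$, pin the internal radii:

$$R_c^2 = R_o^2 - 3R_n^2 + 2R_n^3/R_o, \qquad
  \bar R^2 = R_o^2 - R_i^2 - 2R_n^3\!\left(\tfrac1{R_i}-\tfrac1{R_o}\right).$$

$\bar R$ is the outer radius at which the inhibited region first forms.
Two interpretations of the inhibited region are supported by the same
machinery: an oxygen threshold $p_i$ (then
$\bar R^2 = R_c^2 (p_\infty - p_i)/p_\infty$) or a waste threshold
$\beta_i$ (then $\bar R^2 = 6\beta_i\kappa/P$, independent of oxygen).
The solver is agnostic: it consumes $(R_c, \bar R)$ however constructed.

Conservation of volume drives the outer radius:

$$R_o^2\,\frac{dR_o}{dt} = \frac{s}{3}\left[R_o^3 -
  \max(R_i^3, R_n^3)\right] - \lambda R_n^3,$$

where $s$ (day$^{-1}$) is the volume production rate by mitosis per unit
living volume and $\lambda$ (day$^{-1}$) the rate of volume loss from the
core. The `max` is implemented literally so regimes with $R_n > R_i$
remain representable. The five-parameter vector is
$(R_o(0), s, R_c, \gamma, Q)$ with $\gamma = \lambda/s$ and
$Q = \bar R / R_c$; `greenspan_params()` accepts either member of each
bijective pair. During the exponential phase
$R_o(t) = R_o(0)e^{st/3}$, so the inhibited region forms at
$t = (3/s)\log(\bar R / R_o(0))$ — under the waste interpretation a time
independent of the oxygen parameters.

### Switching models

A deoxygenation experiment switches the ambient pressure instantaneously
at $t_s$ (transfer between incubators takes minutes; internal oxygen
re-equilibrates in seconds — both instantaneous on the growth timescale).
Immediately after the switch the oxygen field dictates a larger
quasi-steady core $R_n^+ > R_n$ (`predicted_necrotic_radius()`), and cells
in the newly anoxic shell $R_n < r < R_n^+$ die at a per-volume rate
$\hat\lambda(t) = \hat\lambda_0\, e^{(t - t_s)/\tau_{\hat\lambda}}$,
growing so that the core converges onto $R_n^+$. The core volume obeys

$$\frac{dV_n}{dt} = 3\hat\lambda(t)\left[\tfrac{4\pi}{3}R_n^{+3} -
  V_n\right] - 3\lambda(t) V_n, \qquad R_n = (3V_n/4\pi)^{1/3},$$

with the bracket clamped at zero so the shell term never runs backwards.
Because calibrated rates differ between normoxia and hypoxia, the four
rate-like quantities relax exponentially between their endpoint values
(`relax()`): $\alpha$ (carried in lumped form, equivalently the pair of
critical radii $R_{c,n}$, $R_{c,h}$ each defined at its own ambient
pressure), $\bar R$, $s$ and $\lambda$, with timescales $\tau_\alpha,
\tau_{\bar R}, \tau_s, \tau_\lambda$ — fifteen free parameters in all
(`deoxygenation_params()`).

Re-oxygenation mirrors this. The governing equations for the post-switch
system are constructed by strict analogy with the deoxygenation system
under three mechanisms: the quasi-steady core shrinks ($R_n^+ < R_n$), the
re-oxygenated shell $R_n^+ < r < R_n$ clears at rate
$\tilde\lambda(t) = \tilde\lambda_0\, e^{(t-t_s)/\tau_{\tilde\lambda}}$,
and a fraction $\nu \in [0,1]$ of the cleared volume recovers as living
cells while $1-\nu$ leaves the spheroid. In volume form the outer-radius
balance becomes
$\dot V_o = s(V_o - V_{\max}) - 3\lambda V_n - (1-\nu)\,3\tilde\lambda\,
(V_n - V_n^+)_+$, which is the unique form consistent with exact volume
bookkeeping at both $\nu = 0$ (all cleared volume leaves) and $\nu = 1$
(clearance only converts necrotic to living volume). $\lambda$ is taken to
act on the whole core, not only its still-anoxic part — the simpler
reading, and the two are indistinguishable once the core has relaxed.
Seventeen free parameters (`reoxygenation_params()`), including the
initial core radius $R_n(0)$.

Because the constant-environment model carries an *algebraic* core while
the switching models carry a *dynamic* one, a free $R_n(0)$ needs a
channel pulling the core toward its quasi-steady value whenever no
clearing shell exists. A fast first-order tracking rate
$\lambda_{\mathrm{eq}}$ (default 50 day$^{-1}$, i.e. equilibration within
about half an hour) serves both for the pre-switch segment and for
late-time core re-formation after transient clearance. It is a numerical
coupling constant, not a biological parameter; its steady-state tracking
error is of order $\lambda/\lambda_{\mathrm{eq}} < 2\%$ in volume,
well below measurement noise.

This construction reproduces the defining qualitative behaviours: after
deoxygenation the outer radius stays approximately constant while the
internal fractions $\xi_n = R_n/R_o$, $\xi_i = R_i/R_o$ grow toward their
hypoxia values, and after re-oxygenation a trajectory can pass through the
growth phases in reverse (iii $\to$ ii $\to$ i) before growing back
through them in order.

## Numerical choices

* **Index reduction, not a DAE integrator.** The algebraic constraints
  have unique roots in the valid bracket ($[0, R_o)$ for the core,
  $[R_n, R_o)$ for the inhibited radius; both constraint functions are
  strictly monotone there), so they are resolved inside the right-hand
  side by a bisection-safeguarded Newton iteration (absolute tolerance
  well below $10^{-9}\,\mu$m) and the system is integrated as a one- or
  two-state ODE.
* **Integrator.** Adaptive Cash–Karp Runge–Kutta 4(5) in compiled code,
  default tolerances rtol $10^{-8}$ / atol $10^{-10}\,\mu$m. Halving the
  tolerances moves an eight-day trajectory by under $10^{-3}\,\mu$m.
* **Events.** Region-formation times (crossings of $\bar R$ and $R_c$ by
  $R_o$) are located by bisection with re-integration from the bracketing
  step, resolving them far below the contract of $10^{-6}$ days.
* **Exponential-rate cap.** $\hat\lambda(t)$ and $\tilde\lambda(t)$ grow
  without bound by design; once they exceed every other rate by orders of
  magnitude the dynamics are indistinguishable from perfect tracking of
  $R_n^+$, while the stiffness would throttle an explicit method. Both are
  capped at 500 day$^{-1}$; the induced tracking error is
  $\sim\lambda/500 \approx 0.2\%$ in volume.
* **Phase labels on switching trajectories** use a 0.5 µm threshold for
  "region present": the dynamic core volume decays exponentially during
  clearance and never reaches exactly zero, and half a micrometre is far
  below both cell size and measurement resolution. Snapshot
  classification (`classify_phase()`) remains exact.
* **Ties at phase boundaries** resolve to the smaller region: at
  $R_o = R_c$ exactly, $R_n = 0$.
* **Noisy tables with $R_i < R_n$** are kept (and reported by
  `validate_measurements()`) but clipped to $R_i = R_n$ for profile
  evaluation, with a warning.

## Calibration workflow

* **Outliers** are flagged per condition, channel and day by the
  1.5 IQR quartile rule, with quartiles by linear interpolation of order
  statistics (type-7). The rule, not the quartile convention, is the
  contract.
* **Likelihood.** Independent Gaussian errors with one shared standard
  deviation across $R_o$, $R_n$, $R_i$ (a per-channel option exists); the
  hypoxic radius $R_p$ never enters a fit — it serves only to validate the
  estimated oxygen field. Missing values contribute nothing.
* **MLE** by multistart L-BFGS-B on the profiled deviance (the sum of
  squared residuals) from Latin-hypercube starts within bounds;
  deterministic per seed; $\hat\sigma^2 = \mathrm{SSR}/N$.
* **Profile likelihood** re-optimises all nuisance parameters on a grid
  swept outward from the MLE with warm starts; the 95% interval is the
  region above $-1.92$ (the $\chi^2_1$ cutoff, from the standard
  identifiability methodology), with edges refined by root-finding
  between grid points. Non-unimodal profiles are returned with a warning,
  never an error.
* **Posterior sampling** by adaptive Metropolis: a multivariate Gaussian
  random walk whose covariance adapts to the running sample covariance
  (scaled $2.38^2/d$), uniform priors on the search bounds, and the error
  variance sampled between parameter updates from its conjugate
  inverse-gamma conditional under a scale-invariant prior. Acceptance
  rates outside $[0.05, 0.6]$ raise a warning.
* **Convergence** via the Gelman–Rubin potential scale reduction factor.
  The implementation uses $\hat R = \sqrt{1 + B/(nW)}$, the classic
  between/within variance ratio with its $(n-1)/n$ finite-sample factor
  normalised so that chains identical to each other give exactly 1;
  values at or below 1.1 are taken as converged.
* **Prediction intervals** simulate posterior draws over a time grid,
  optionally adding observation noise, and report central bands at the
  50, 75, 95, 97.5 and 99.5% levels.
* **Staged deoxygenation calibration**
  (`staged_deoxygenation_calibration()`) narrows the fifteen-dimensional
  search the way a practitioner would: normal fit to first-day sizes;
  per-spheroid snapshot estimates of $R_c$ and $\bar R$ in the constant
  conditions; constant-environment posteriors for the endpoint rates;
  relaxation-form fits to per-snapshot series from the switching data
  (assuming $R_n = R_n^+$, which the shell-death mechanism makes accurate
  within a day of the switch) for the adaptation timescales; then the
  full model fit inside bounds informed by all of the above; finally a
  posterior-predictive coverage check.

## The synthetic-data generator

`generate_dataset()` emulates destructive end-point imaging: each
(day, spheroid) pair is an independent draw of the model trajectory plus
iid Gaussian noise per channel (default $\sigma = 4\,\mu$m), truncated at
zero; radii of unformed regions are recorded as 0 exactly, matching the
measurement convention. The condition presets reproduce the emulated
study layouts — normoxia: days 2, 3, 4, 6, 8 with 12 spheroids per day;
hypoxia: days 2, 4, 6, 8 with 7 per day; the switching layouts (not fully
specified by the published designs) use the normoxia layout with
$t_s = 2$ for deoxygenation and 7 spheroids per day with $t_s = 2$ for
re-oxygenation. The hypoxic radius is synthesised from the predicted
oxygen field at a configurable marker threshold (default 0.5%) — the
threshold of the staining marker is not a published number, so it is a
config entry. Injected outliers (a multiplicative factor on a random
subset) exercise the filtering rule.

The `ground_truth_bundle()` presets are package fixtures with magnitudes
plausible for melanoma spheroids (initial radii near 100 µm, saturation
at a few hundred µm within eight days, hypoxia saturating smaller and
earlier than normoxia, adaptation timescales of a quarter-day for the
oxygen-linked quantities). The switching presets were chosen once so that
the behaviours the models exist to describe are present — the post-switch
jump $R_n^+ > R_n$, the stalled outer radius with growing core fraction,
and the transient phase reversal.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: biological between-spheroid variability
beyond measurement noise (no random effects), non-Gaussian or
channel-correlated measurement error, asymmetric necrotic-core
translocation and expulsion (observed in some re-oxygenated cell lines;
explicitly outside the spherically symmetric model), and image-processing
artefacts upstream of the radii.

## Problem sizes

The test-suite and acceptance computations use desk-scale sizes chosen to
exercise every stage at full fidelity: four chains of 20,000 samples with
5,000 burn-in for the headline convergence check (study-scale runs of
4 × 250,000 with 50,000 burn-in are a parameter change); 30 synthetic
replicates for the profile-interval coverage experiment; 1,000 random
instances for the root-inversion oracles; $10^4$-point grids for the
finite-difference field oracle; staged calibration with 2 × 4,000-sample
chains per stage.

## Known limitations

Spherical symmetry throughout; constant consumption and production rates
within a region; the re-oxygenation post-switch system is one reasonable
construction of the stated mechanisms and is isolated behind
`solve_reoxygenation()` so an alternative bookkeeping (e.g. recovered
volume credited to the inhibited shell) could be swapped in; a single
shared error standard deviation is the default even though channel noise
plausibly differs; and profile-likelihood intervals are approximate
(asymptotic $\chi^2$ calibration).
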