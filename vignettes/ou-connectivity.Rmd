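---
title: "Stochastic-dynamics connectivity: model, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic-dynamics connectivity: model, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ouconn)
```

## The model and its assumptions

`ouconn` treats an N-channel resting-state recording as a stationary linear
stochastic system — a multivariate Ornstein–Uhlenbeck (OU) process:

$$\frac{dx}{dt} = W x + \xi(t), \qquad
  \langle \xi(t)\,\xi(t')^\top \rangle = Q\,\delta(t - t').$$

The drift operator $W$ (1/s) is read as directed functional connectivity:
$W_{ij}$ is the net effect of channel $j$'s activity on the rate of change of
channel $i$'s, its sign a *functional* excitation or inhibition. The driving
noise $\xi$ is temporally white but spatially correlated, with covariance
$Q$. The modelling assumptions are:

1. **Linearity around an equilibrium.** Without stimulation, activity
   fluctuates around a stable fixed point; the linearisation is the model.
   This restricts validity to resting-state epochs.
2. **Stability.** All eigenvalues of $W$ must have negative real parts;
   the largest real part sets the slowest relaxation (sub-second for resting
   recordings). An estimated non-negative maximum is reported as a warning
   flag (`stability_spectrum`), never an error: sampling noise can push a
   marginally stable estimate over the line.
3. **White, Gaussian residuals.** If the fit is adequate, the extracted
   residuals must be Gaussian and temporally uncorrelated
   (`residual_diagnostics` checks both); structure left in the residuals
   indicates dynamics the linear model cannot absorb.

## Estimators

For a stationary OU process the lagged covariance with the future-times-past
orientation $C(\tau) = \langle x(t+\tau)\,x(t)^\top\rangle$ satisfies
$C(\tau) = e^{W\tau} C(0)$. For lags small against the dynamics,
$e^{W\tau} \approx I + W\tau$, giving

$$\hat W = \bigl(C(\tau)\,C(0)^{-1} - I\bigr)/\tau .$$

The orientation of $C(\tau)$ is forced by this identity; the covariance
estimator subtracts channel means and divides by the number of overlapping
sample pairs minus one. If $C(0)$ is numerically rank-deficient (duplicated
or linearly dependent channels) its Moore–Penrose pseudo-inverse is used,
truncating singular values below $10^{-10}$ of the largest.

Residuals use the forward difference, consistent with the same small-lag
expansion: $r(t) = (x(t+\tau) - x(t))/\tau - \hat W x(t)$. Two noise
covariances are computed and compared (`noise_agreement`):

* empirical, $Q_E = \tau\,\mathrm{Cov}(r)$ — the $\tau$ factor converts the
  discrete residual covariance to the continuous-time diffusion convention
  $\langle\xi\xi^\top\rangle = Q\delta$, a normalization the package
  validates by simulation recovery (a scalar OU with diffusion $q$ returns
  $Q_E \to q$);
* theoretical, from the stationary Lyapunov identity
  $Q_T = -(W C_0 + C_0 W^\top)$.

Their entrywise correlation near 1 on fitted data is the model's
self-validation.

### Lag choice

`select_lag` fits each candidate lag and minimises the trace of $Q_E$, ties
toward the smallest lag. One mathematical fact deserves emphasis: **on data
that exactly follow a linear Gaussian process, this trace decreases
monotonically with the lag** (for a normal drift with decay $\lambda$ it is
$\propto (1 - e^{-2\lambda\tau})/(2\lambda\tau)$), so the selector picks the
largest candidate on simulated data. The smallest-lag minimum observed on
real recordings is therefore a signature of real-data departures from the
model (bandlimited sensors, nonstationarity), not of the model itself. For
this reason the package *defaults to a fixed lag of one sample* and treats
`select_lag` as a diagnostic, verified in tests against brute-force
recomputation rather than against an assumed location of the minimum.

### Finite-lag bias

The small-lag expansion biases $\hat W$ by $\approx W^2\tau/2$ (verified on
a lag grid for the scalar OU in the test suite) and $Q_E$ by
$\approx (WQ + QW^\top)\tau/2$. Both vanish as $\tau \to 0$; at 625 Hz they
are at the percent level provided the drift's spectral radius stays well
below the sampling rate — the reason for the simulator's coupling
normalization below.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `dt` | 1/625 s | sampling interval; set by the acquisition system |
| `lag_steps` | 1 sample | fitting lag $\tau = $ `lag_steps * dt` |
| `duration` | 30 s | simulated epoch length (one resting epoch) |
| `n_perm` | 10 000 | permutations per connection-wise test |
| `n_perm` (labels) | 10 000 (500 in tests) | label permutations per classifier report |
| `cost` | $10^4$ | SVM soft-margin cost; effectively hard margin |
| `correlation_length` | 0.06 / 0.18 m | noise kernel length scales (control / patient worlds) |
| `jitter_sd` | 0.5 /s | subject-level coupling jitter |
| `target_max_real_part` | −2.5 /s | generator relaxation rate (0.4 s, sub-second) |

## What the simulator emulates — and what it does not

`synthesize_cohort` produces the *stated world* of a small case/control
resting-state study: 10 + 9 subjects, 30 s epochs at 625 Hz, a shared sensor
layout (141 sensors on a spherical cap, stereographically projected to a
disc), per-subject drift matrices (shared base + planted group deltas +
Gaussian jitter, resampled if unstable), and group-specific noise covariances
from a squared-exponential kernel over the projected layout.

Design choices made here, and why:

* **Exact sampling.** The default scheme draws the discretely observed
  process exactly: $x_{t+1} = A x_t + \eta$, $A = e^{W\,dt}$,
  $\mathrm{Cov}(\eta) = C - ACA^\top$ with $C$ the stationary Lyapunov
  solution, initial state from the stationary law. Recovery tests are then
  sharp — any estimator error is the estimator's fault, not the
  integrator's. An Euler–Maruyama scheme is kept for convergence checks; its
  stationary covariance provably approaches the exact one as $dt \to 0$, and
  the tests verify this at the population level (simulating long enough to
  detect an $O(\lambda\,dt)$ covariance discrepancy by Monte Carlo would be
  wasteful).
* **Skew-dominant couplings** (`skew_frac = 0.95`). Resting recordings are
  rhythmic; a drift whose off-diagonal couplings are mostly antisymmetric
  behaves as a bank of damped oscillators (complex eigenvalues), which is
  both the realistic regime and the identifiable one: near-normal drifts
  keep every mode of the stationary process comparably excited, so a 30 s
  record determines $W$ to ~10 % relative error at $N = 10$. With
  symmetric-heavy couplings some modes decay too fast to be observed and the
  same criterion is mathematically unreachable at 30 s.
* **Mean-field coupling scale** (`coupling_sd = 120/N`). Per-coupling
  strength scales as $1/N$ so each node receives an $O(1)$ total drive
  regardless of how finely the scalp is sampled. This keeps relaxation and
  oscillation time scales N-independent (a 141-sensor grid of the same brain
  should not oscillate 4× faster than a 10-sensor one) and keeps
  $\|W\|\,\tau$ small, so the small-lag estimator premise holds at every N
  used in the tests.
* **Subject jitter** (sd 0.5/s on nonzero couplings) creates the
  within-group spread that the connection-wise permutation tests need;
  unstable draws are rejected and resampled (up to 100 attempts).
* **Planted contrasts.** Group differences are planted both in specific
  connections (additive deltas on $W$, default 4/s) and in the noise
  correlation length (0.06 m vs 0.18 m on a 0.36 m-diameter projected disc),
  emulating a patchy-vs-extended background-noise contrast.

Not emulated: sensor physics (lead fields, gradiometer geometry, sensor
noise floors), artifacts (the PCA artifact-removal operation is exercised on
planted rank-1 contaminants instead), nonstationarity, and inter-subject
anatomical variability. A green simulator test therefore establishes that
the *estimators and statistics* behave as designed on data satisfying the
model — it cannot establish that real recordings satisfy the model; that is
what the residual diagnostics and the $Q_E$/$Q_T$ agreement are for on real
data.

## Statistics

* **Connection-wise permutation test.** For each ordered pair, the pooled
  per-subject couplings are re-partitioned at random into surrogate groups
  (10 000 draws by default); the z-score is the observed mean difference over
  the null standard deviation (divisor $n_\mathrm{perm} - 1$). Both the
  left-tail p (the null construction's convention) and a two-sided p are
  reported; significance statements use the two-sided p, since the change
  maps weight by $|z|$ symmetrically. No multiple-comparison correction is
  applied across the $N^2$ tests — a deliberate, documented caveat: the maps
  are descriptive, the cohort-level inference comes from the classifier
  permutation test.
* **Relative change maps** divide by the absolute control-group mean and
  mask entries where that baseline is below $10^{-3}$ of the median absolute
  baseline, rather than report near-infinite relative changes.
* **Classifier.** Linear maximal-margin SVM (in-package deterministic
  SMO-type dual ascent — no external SVM dependency), no feature
  standardization, patient group as positive class, leave-one-out
  cross-validation; metrics are *truncated* to integer percent (16/19 →
  84), matching how such tables are conventionally printed; significance by
  full-LOOCV label permutation, $p$ = fraction of permuted runs with metric
  $\geq$ observed. A fold whose training set lost a class counts its
  held-out subject as misclassified.
* **Rank-sum comparisons** of scalar summaries (stability, complexity,
  cross-talk r) use midranks and exact enumeration up to
  $\binom{n+m}{n} \le 5000$, the normal approximation with continuity and
  tie corrections beyond.

## Noise spatial structure

The dominant noise pattern is the eigenvalue-weighted average of $Q$'s
eigenvectors (weights normalized to sum 1). Eigenvectors are sign-ambiguous;
each is oriented so its largest-magnitude component is positive. A spectrum
with numerically repeated eigenvalues (within $10^{-8}\lambda_{max}$) is
flagged `degenerate`: the pattern is then reported but marked
non-informative rather than silently arbitrary.

Spatial complexity is the root-mean-square leave-one-out interpolation
error: each sensor's value is predicted from all the others by a
biharmonic-spline radial basis interpolant ($\varphi(r) = r^2(\ln r - 1)$)
**augmented with an affine tail** $(1, x, y)$ under the usual orthogonality
side conditions. The augmentation is this package's design choice: the bare
RBF system does not reproduce constant or planar fields exactly, whereas
with the affine tail a constant pattern scores exactly 0 and a planar ramp
scores (numerically) 0 — so the statistic measures curvature-like
heterogeneity, is invariant under adding constants, homogeneous of degree 1,
and invariant under sensor relabeling. "Neighbours" means all remaining
sensors by default; a k-nearest option exists but collinear support sets can
make the augmented system singular, so the default is recommended.

Empirically (and by construction), complexity falls as the generating noise
correlation length grows; the test suite verifies strictly ordered medians
over ℓ ∈ {2, 6, 18} cm on the 141-sensor layout through the full
simulate–fit–pattern–score loop.

## Numerical choices and degenerate inputs

* Lyapunov equations are solved by eigendecomposition of $W$ (complex-safe),
  with a Kronecker-system fallback for defective drifts.
* Matrix exponentials and PSD square roots also go through
  eigendecompositions; negative PSD eigenvalues are clipped at zero.
* Degenerate permutation nulls (all pooled values equal) return $z = 0$,
  two-sided $p = 1$, flagged. Constant matrices give a flagged `NaN`
  noise-agreement. Zero-variance balance vectors give `NA` correlations.
* All randomness flows from explicit integer seeds; per-stage sub-seeds are
  derived deterministically, so identical configuration + seed reproduces a
  byte-identical report bundle.

## Known limitations

* The linear model is blind to nonlinear or task-modulated coupling; it is a
  resting-state tool by construction.
* At 625 Hz the one-sample-lag estimator carries an $O(\|W\|\tau)$ bias —
  negligible for sub-second relaxation, visible if dynamics approach the
  sampling rate.
* Sensor-space coupling is not source-space coupling: cross-talk inflates
  short-range covariance (quantified by `crosstalk_profile`), which is why
  group *differences*, not absolute couplings, are the unit of
  interpretation.
* With ~19 subjects and ~20 000 features, the classifier operates in the
  always-separable regime; only the permutation p-values, not the raw
  accuracies, carry inferential weight.
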