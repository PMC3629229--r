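# ouconn

Directed functional connectivity and background-noise structure from
multivariate Ornstein–Uhlenbeck fits to resting-state recordings.

## The problem

Resting-state brain activity recorded over many sensors (MEG/EEG) looks like
noise-driven fluctuations around an equilibrium. `ouconn` models an
N-channel recording as a linear stochastic system — a multivariate
Ornstein–Uhlenbeck process,

    dx/dt = W x + ξ(t),        ⟨ξ(t) ξ(t′)ᵀ⟩ = Q δ(t − t′)

where `x` is the vector of channel signals relative to baseline, `W` (units
1/s) is the drift operator read as a *directed* functional-connectivity
matrix (`W[i, j]` = coupling from channel `j` onto channel `i`, sign =
functional excitation/inhibition), and `ξ` is spatially correlated, temporally
white Gaussian background noise with covariance `Q`. Fitting this model gives
two complementary fingerprints of a brain at rest: the deterministic coupling
`W` and the spatial structure of the stochastic drive `Q` — both usable to
discriminate groups (e.g. patients vs controls).

## What the package does

* **Fit** (`fit_subject`): for a stationary process the lagged covariance
  obeys `C(τ) = e^{Wτ} C(0)`, so for small lags
  `Ŵ = (C(τ) C(0)⁻¹ − I)/τ` (pseudo-inverse fallback for rank-deficient
  `C(0)`). Residuals `r(t) = (x(t+τ) − x(t))/τ − Ŵ x(t)` give the empirical
  noise covariance `Q_E = τ · Cov(r)`, checked against the stationary
  Lyapunov identity `Q_T = −(Ŵ C(0) + C(0) Ŵᵀ)`.
* **Diagnostics**: stability spectrum of `Ŵ` (all eigenvalue real parts must
  be negative for a valid resting-state fit), residual Gaussianity/whiteness,
  excitation/inhibition balance (`I±`, `O±` node sums and their
  correlations), covariance-vs-distance cross-talk profiles.
* **Group statistics** (`connectionwise_changes`, `rank_changes`,
  `ranksum_compare`): connection-wise random-permutation tests with
  z-scores, z-weighted absolute and relative change maps, ranked dominant
  changes ("arrow plot" tables).
* **Classification** (`feature_set`, `loocv_evaluate`,
  `label_permutation_significance`): vectorized `W` or `Q` matrices
  (141×141 → 19 881 features) into a linear maximal-margin SVM under
  leave-one-out cross-validation, with label-permutation p-values for
  accuracy/specificity/sensitivity/F-score.
* **Noise spatial structure** (`dominant_noise_pattern`,
  `spatial_complexity`): the eigenvalue-weighted average of `Q`'s
  eigenvectors as a per-sensor pattern, and its leave-one-out
  biharmonic-spline interpolation error as a spatial-complexity score (low =
  spatially extended noise correlations, high = patchy).
* **Simulator** (`synthetic_layout`, `random_stable_connectivity`,
  `spatial_noise_covariance`, `simulate_moup`, `synthesize_cohort`): exact
  (discretisation-error-free) sampling of stationary OU cohorts with planted
  connection differences and group-specific noise correlation lengths, so
  the whole pipeline is testable end to end without any data download.
* **Pipeline & CLI** (`run_full_comparison`, `ouconn_cli`, `inst/exec/ouconn`):
  manifest-driven end-to-end runs with deterministic seeding; subcommands
  `simulate`, `fit`, `noise`, `classify`, `compare`, `complexity`, `run-all`.

## Worked example

```r
library(ouconn)
lay    <- synthetic_layout(10)                                   # 10 sensors
W_true <- random_stable_connectivity(10, target_max_real_part = -2.5, seed = 3)
Q_true <- spatial_noise_covariance(lay, correlation_length = 0.06)
rec    <- simulate_moup(W_true, Q_true, dt = 1/625, duration = 30, seed = 4)
rec
#> <mc_recording> 10 channels x 18750 samples, dt = 0.0016 s (30 s)

fit <- fit_subject(rec)
fit
#> <conn_matrix> 10 x 10 drift operator (1/s), lag 0.0016 s, max Re(lambda) = -2.527 (stable)
#> <noise_model> 10 channels x 18749 residual samples; Q_E/Q_T agreement r = 0.9970

norm(fit$W$W - W_true$W, "F") / norm(W_true$W, "F")
#> [1] 0.101

residual_diagnostics(fit$noise)
#> <residual_diagnostics> 18749 samples; |skewness| <= 0.039; whiteness score 0.0188 (4/sqrt(T) = 0.0292)

spatial_complexity(dominant_noise_pattern(fit$noise$Q_empirical), lay)
#> [1] 0.0814
```

Reading the numbers: the fitted drift is stable with slowest relaxation
1/2.53 ≈ 0.4 s; the 30 s record recovers the true 10×10 drift to ~10 %
relative Frobenius error; residuals are white (max off-zero autocorrelation
0.019, under the ~4/√T sampling band) and symmetric (|skewness| ≤ 0.04), and
the noise covariance measured from residuals agrees with the one predicted
from the fitted drift at r = 0.997 — the model self-validates. The spatial
complexity scalar summarizes how patchy the dominant noise pattern is; on
cohorts it is compared between groups with `ranksum_compare`.

A full two-group analysis is one call:

```r
spec   <- cohort_spec(n_control = 10, n_patient = 9, layout = synthetic_layout(12),
                      deltas = data.frame(i = 5, j = 2, delta = 6), seed = 1)
cohort <- synthesize_cohort(spec)
run_full_comparison(cohort, n_perm = 500, n_perm_labels = 200, seed = 1)
#> <comparison_bundle>
#>   channels: 12, subjects: 10 control + 9 patient
#>   top |z|-weighted change: s002 -> s005 (...)
#>   W classifier accuracy: 84% (p = 0)
#>   Q classifier accuracy: 100% (p = 0)
#>   complexity medians: control 0.068 vs patient 0.0119 (ranksum p = 0.00028)
```

The planted connection (2 → 5) tops the ranked changes, the noise-covariance
features separate the groups at least as well as the connectivity features,
and the group with long-range noise correlations scores significantly lower
spatial complexity — the qualitative pattern the method is designed to
detect.

## Command line

```sh
inst/exec/ouconn simulate --config cohort.json --seed 1 --out-dir sim/
inst/exec/ouconn run-all  --manifest sim/manifest.json --n-perm 1000 --out-dir out/
```

See `vignettes/ou-connectivity.Rmd` for the model assumptions, parameter
choices, and limitations.
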