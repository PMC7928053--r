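# mhemuscle

Real-time, dynamically consistent estimation of muscle forces by moving
horizon EMG–marker tracking.

## The problem

Muscle forces cannot be measured non-invasively. The standard estimation
chains — inverse kinematics, then inverse dynamics, then static
optimization or EMG-driven forward simulation — process each measurement
modality in sequence, so errors accumulate and the reconstructed motion,
activations and forces are not mutually consistent with the skeleton's
equations of motion. `mhemuscle` instead solves one estimation problem
over a short receding window of data, fusing surface EMG envelopes and
skin-marker trajectories simultaneously under the full muscle-actuated
dynamics.

At each window position the estimator solves

```
min_{x, u}   Σ_k  ω_m ||m(q_k) − m̃_k||²  +  ω_e ||u_k − ẽ_k||²
             + regularization + joint-limit penalty
s.t.         x_{k+1} = F(x_k, u_k)          (RK4 muscle-actuated dynamics)
             0 ≤ u_k ≤ 1,   x_0 given by the previous window
```

where `x = (q, q̇, a)` stacks joint angles, velocities and muscle
activations, `u` are muscle excitations, `m(q)` is marker forward
kinematics and `m̃, ẽ` are the measurements. Because the dynamics are a
hard constraint, the estimated states, activations and forces are
consistent with each other by construction; the one-step integration
residual of a returned estimate is exactly zero. Successive windows are
warm-started and chained through their initial state (Algorithm-1-style
moving horizon estimation), so the whole trajectory is produced causally,
window by window, as data arrive.

Three cost variants are provided as `cost_weights()` presets:

* `track_emg_high_marker` — marker weight 1e9, EMG tracked (the reference
  configuration);
* `track_emg_low_marker` — marker weight 1e7;
* `min_excitation` — EMG term replaced by a minimum-excitation objective,
  i.e. classical static-optimization behavior embedded in the same MHE.

## What is in the package

* **Musculoskeletal core** (`arm_model()`, 4 DoF / 19 muscles;
  `planar_arm_model()`, 2 DoF / 6 muscles): serial-chain forward
  kinematics, polyline muscle geometry with analytic moment arms,
  rigid-tendon Hill force generation (Gaussian force–length, hyperbolic
  force–velocity, smooth passive element), first-order
  activation/deactivation dynamics with excitation delay, recursive
  Newton–Euler rigid-body dynamics, RK4 integration. All numerics in
  C++ (Rcpp/RcppArmadillo).
* **Reference generator** (`generate_reference()`): cyclic arm motions
  solved by optimal control so that the synthetic "measurements" exactly
  satisfy the model dynamics, with four co-contraction levels implemented
  as excitation floors on the elbow antagonists.
* **Noise simulator** (`noise_spec()`, `corrupt_reference()`):
  low-frequency Fourier-domain EMG noise (all coefficients below
  2.125 Hz perturbed by conjugate-symmetric complex Gaussians) and
  marker placement error (a one-time Gaussian displacement of each
  marker on a surrogate model, then re-simulated trajectories).
* **Estimator** (`mhe_problem()`, `run_mhe()`, `mhe_init()`/`mhe_step()`
  for live streaming, `full_window_estimate()` for the non-causal
  baseline): condensed Gauss–Newton / Levenberg–Marquardt with bound
  handling, stale-Jacobian reuse and warm starting.
* **Evaluation** (`rmse()`, `score_run()`, `window_sweep()`,
  `experiment_grid()`, `run_grid()`, `anova_two_way()`,
  `anova_three_way()`): RMSE scoring in degrees / newtons / meters, the
  >90 % convergence exclusion rule, window-size sweeps with the
  real-time subsampling rule, fully crossed noise grids, and ANOVA with
  Bonferroni post hocs.
* **IO and CLI** (`write_reference()`, marker/EMG/model readers and
  writers, `cli_main()` plus the `inst/cli/mhe` launcher): CSV
  time-series with unit headers, YAML models, JSON sidecars with model
  hashes.

Tabular results are tibbles; fits and references have `tidy()`,
`glance()` and `autoplot()` methods.

## Worked example

A 2-DoF planar arm, a 4 s cyclic reference with mid co-contraction,
mid-level EMG and marker-placement noise, and a window-7 estimate at half
the native rate:

```r
library(mhemuscle)

model <- planar_arm_model()
ref <- generate_reference(model, duration = 4, n_nodes = 200,
                          cocontraction = "mid",
                          cocontraction_muscles = c("ELFLX", "ELEXT",
                                                    "BIFLX", "BIEXT"))
ref
#> <ref_dataset> 200 intervals over 4 s (50 Hz), co-contraction: mid

spec   <- noise_spec(emg_level = "mid", marker_level = "mid", seed = 7)
stream <- subsample_stream(corrupt_reference(ref, spec), 2)
fit    <- run_mhe(stream, mhe_problem(model, window = 7))
glance(fit)
#> # A tibble: 1 × 8
#>   n_solves convergence_rate achieved median_iterations window    dt formulation
#>      <int>            <dbl> <lgl>                <int>  <int> <dbl> <chr>
#> 1       95                1 TRUE                     5      7  0.04 excitation

score_run(fit, ref)
#> # A tibble: 1 × 5
#>   rmse_q_deg rmse_force_n rmse_markers_m convergence_rate kept
#>        <dbl>        <dbl>          <dbl>            <dbl> <lgl>
#> 1       1.38         11.4        0.00183                1 TRUE
```

With the noise switched off the same pipeline recovers the reference
almost exactly — `rmse(fit, ref, "angles")` is 3.2e-4 deg,
markers 5.2e-4 mm — which is the self-consistency check that the
estimator, generator and model all share one set of discrete dynamics.
`autoplot(fit, ref = ref)` and `plot_forces(fit, ref)` overlay estimates
on the ground truth; `window_sweep()` and `run_grid()` scale this up to
the full study design.

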