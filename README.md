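# trunksyn

Estimation of unmeasured **trunk muscle activations during gait** from
lower-extremity muscle synergies.

Gait labs rarely record trunk EMG — channels go to the legs, and several
lumbar muscles are not reachable from the surface — yet musculoskeletal
simulations of walking (for example when planning pelvic surgery or sizing
a custom pelvic prosthesis) need forces for the muscles crossing the
lumbosacral joint. **trunksyn** implements a synergy-based estimator for
exactly this gap, for biomechanists working with OpenSim-style gait data.

## The method

Leg muscle activations of one side, `A (nMusc x nPt)`, are decomposed by
non-negative matrix factorization into `A ≈ W H`, where the k rows of `H`
are time-varying synergy activations (each max-normalized to 1) and `W`
holds nonnegative synergy-vector weights. Assuming the trunk shares the
ipsilateral synergy activations, trunk activations are

    a[t, i] = Σ_s w[i, s] · H[s, t],   w ≥ 0,  0 ≤ a ≤ 1,

and the unknown trunk weights `w` are found by minimizing

    J = J_M + J_a + J_a_dev + J_w_dev

where `J_M` penalizes the mismatch between the lumbosacral moments
generated by the 58 rigid-tendon Hill-type trunk MTUs and the
inverse-dynamics moments (scaled by the 5 Nm allowance `AllowΔM`), `J_a`
penalizes activation magnitude (allowance `Allow_a` ∈ {1.00, 0.75, 0.50,
0.25}), and the deviation terms keep the heads of each of the six muscle
groups per side (RA, ES, QL, MF, EO, IO) acting coherently (allowances
`AllowΔa = AllowΔw = 0.05`). Because `H` is fixed and normalized, the
problem is a convex quadratic program solved in one shot over all time
frames. A per-frame static-optimization baseline (`static_optimization()`),
strength personalization from anatomical cross-sectional areas
(`fmax_from_acsa()`, 100 N/cm²), fiber-length tuning, optimization-based
muscle-set reduction, gait-cycle I/O for OpenSim storage files, moment-RMSE
and electromechanical-delay-swept correlation metrics, and a synthetic
data generator with known ground truth round out the package. See the
methods vignette (`vignettes/trunk-synergy-estimation.Rmd`) for the full
model description and design rationale.

## Worked example

```r
library(trunksyn)
# synthetic gait trial with known ground truth
ds <- make_dataset(syn_spec(n_cycles = 2, seed = 42,
                            activation_noise_sd = 0, moment_noise_sd = 0))
cy <- ds$cycles[[1]]

# extract 7 synergies per side from the leg activations and normalize
synergies <- lapply(c(right = "right", left = "left"), function(s) {
  normalize_activations(
    extract_synergies(cy$leg_activations[[s]], k = 7, seed = 1))
})

# estimate trunk weights so Hill-model moments track inverse dynamics
fit <- syn_estimate(ds$model, cy$M_ID, lapply(synergies, function(s) s$H),
                    syn_control(allow_a = 0.50))
summary(fit)
#> Trunk synergy-weight estimation summary
#>   moment tracking RMSE (Nm): 0.022, 0.025, 0.017
#>   cost total 0.003321 | J_M 1.832e-05 | J_a 0.003291 | J_a_dev 3.682e-06
#>   mean activation by group:
#>  EO.left EO.right  ES.left ES.right  IO.left IO.right  MF.left MF.right
#>   0.0271   0.0352   0.0021   0.0063   0.0248   0.0250   0.0242   0.0122
#>  QL.left QL.right  RA.left RA.right
#>   0.0079   0.0199   0.0476   0.0071
#>   max activation 0.3171; minimally recruited synergies: 0

r <- recovery_correlation(fitted(fit), cy$trunk_true, grouping(ds$model))
mean(r)
#> [1] 1

es <- grouping(ds$model)[["ES.right"]]
sw <- emd_sweep(rowMeans(fitted(fit)[, es]), cy$excitation$right,
                cycle_duration_s = cy$duration_s)
c(sw$delay_ms, round(sw$r, 3))
#> [1] 120.000   0.999
```

Reading the output: the fitted moments track the inverse-dynamics reference
to within ~0.03 Nm per lumbosacral degree of freedom; group-mean estimated
activations correlate essentially perfectly with the generator's ground
truth; and sweeping electromechanical delays over the standard 100–165 ms
grid recovers the 120 ms delay injected into the surrogate "measured"
erector spinae excitation, with r ≈ 1. `coef(fit)` returns the estimated
synergy-vector weights, `fitted(fit)` the trunk activations, and
`plot(fit)` draws estimated vs reference moments per DoF.

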