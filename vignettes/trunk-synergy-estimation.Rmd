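---
title: "Estimating trunk muscle activations from leg-muscle synergies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating trunk muscle activations from leg-muscle synergies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trunksyn)
```

## The problem

Musculoskeletal simulations of walking need activations for the muscles
crossing the lumbosacral (L5–S1) joint, but gait laboratories rarely record
trunk EMG: electrode channels are spent on the legs, and many trunk muscles
are inaccessible to surface electrodes. **trunksyn** implements a
synergy-based estimator for this situation. Its premise is that the
time-varying synergy activations extracted from leg muscle activity are
shared by the ipsilateral trunk muscles, so the only unknowns for the trunk
are time-invariant, nonnegative synergy-vector weights. Those weights are
found by optimization: the trunk musculotendon forces they imply must
generate lumbosacral joint moments that track the moments known from
inverse dynamics.

## The model

### Synergy representation

Leg muscle activations $A \in \mathbb{R}_{\ge 0}^{n_\mathrm{musc} \times
n_\mathrm{pt}}$ for one side are factorized by non-negative matrix
factorization (`extract_synergies()`) into $A \approx W H$ with $k$
synergies: $H$ ($k \times n_\mathrm{pt}$) holds the time-varying synergy
activations and $W$ the nonnegative weights. Each row of $H$ is rescaled to
peak at exactly 1, with the matching column of $W$ scaled inversely so the
product is unchanged (`normalize_activations()`). The factorization
minimizes the Frobenius reconstruction error by multiplicative updates,
keeping the best of (by default) 20 random restarts; with a fixed seed the
result is bit-reproducible. Typical synergy counts for gait are 5–8 per
side, and the package sweeps exactly that range in its evaluation tools.

### Trunk reconstruction and musculotendon mechanics

Trunk activations are built per side as $a_{t,i} = \sum_s w_{i,s} H_{s,t}$
(`activations_from_weights()`), nonnegative by construction and bounded by
1 whenever $\sum_s w_{i,s} \le 1$. The 58 trunk musculotendon units (29 per
side, grouped into RA, ES, QL, MF, EO and IO) are rigid-tendon Hill-type
actuators: with tendon fixed at slack length, the normalized fiber length
is $\tilde{\ell} = (\ell_{MT} - \ell_T^s)/\ell_M^o$, the active
force–length multiplier is the Gaussian $\exp(-(\tilde{\ell}-1)^2/0.45)$,
the force–velocity multiplier is fixed at 1, and force is affine in
activation: $F = F_M^o (a f_\mathrm{act}(\tilde{\ell}) +
f_\mathrm{pass}(\tilde{\ell}))$. Joint moments are
$M_{t,j} = \sum_i r_{t,i,j} F_{t,i}$ (`joint_moments()`).

The passive element defaults to **off** for trunk estimation: fiber lengths
are tuned to operate just below optimal (see *Personalization*), where the
standard passive curve is zero anyway, and a zero passive term keeps
zero-activation moments zero.

### The objective

`syn_estimate()` minimizes, over $w \ge 0$ and subject to $a \le 1$ at
every sample,

$$J = J_M + J_a + J_{a,\mathrm{dev}} + J_{w,\mathrm{dev}}$$

$$J_M = \frac{1}{n_\mathrm{pt} n_\mathrm{DoF}} \sum_{t,j}
\left(\frac{M^\mathrm{est}_{t,j} - M^\mathrm{ID}_{t,j}}
{\mathrm{Allow}_{\Delta M}}\right)^2,\qquad
J_a = \frac{1}{n_\mathrm{pt} n_\mathrm{musc}} \sum_{t,i}
\left(\frac{a_{t,i}}{\mathrm{Allow}_a}\right)^2,$$

with $J_{a,\mathrm{dev}}$ (and analogously $J_{w,\mathrm{dev}}$) summing,
over the 6 muscle groups per side, the mean squared deviation of each
head's activation (weight) from its group mean, scaled by
$\mathrm{Allow}_{\Delta a}$ ($\mathrm{Allow}_{\Delta w}$). Each allowance
makes its term read exactly 1 when deviations sit at the allowed size:

| parameter | default | units | role |
|---|---|---|---|
| `allow_dM` | 5 | Nm | acceptable moment-tracking error, comparable to EMG-driven leg-model errors |
| `allow_a` | 0.50 | – | activation magnitude above which minimization bites; 1.00/0.75/0.50/0.25 span weak-to-strong effort minimization |
| `allow_da` | 0.05 | – | acceptable head-to-group-mean activation deviation |
| `allow_dw` | 0.05 | – | acceptable head-to-group-mean weight deviation |

The weight-deviation term is included by default because an allowance is
defined for it; `syn_control(include_jw_dev = FALSE)` gives the literal
three-term objective. Both modes are supported because the printed
objective and the stated allowances are reconcilable either way.

### Why the solver is a single convex solve

Because $H$ is fixed and max-normalized, activations — and therefore
estimated moments — are *linear* in $w$. Every term of $J$ is then a convex
quadratic in $w$, the bounds $w \ge 0$ are a cone, and $a \le 1$ is a set
of linear inequalities: the whole problem is a convex QP with a unique
optimal value. All time frames are solved simultaneously. The
implementation stacks the terms as one least-squares system, forms the
normal equations, and minimizes with bounded quasi-Newton (L-BFGS-B,
analytic gradients, $w \ge 0$ as native bounds) started at $w = 0$ — which
also guarantees the returned objective never exceeds the all-zero
solution's. Multi-starts would hedge non-convexity that this formulation
does not have, so none are used. The $a \le 1$ constraints are inactive in
normal data (the activation-minimization term keeps solutions interior);
when they bind, an augmented-Lagrangian outer loop enforces them to 1e-8.

### Static-optimization baseline

`static_optimization()` implements the conventional comparator: per frame,
minimize $\sum_i a_i^2$ subject to exact moment equality on all DoFs and
$0 \le a \le 1$, solved by augmented Lagrangian with a bounded inner
solver. Infeasible frames stop with an error naming the frame unless
reserve actuators are enabled (quadratic penalty weight 1000 on reserve
torques). Because frames are independent, its activation estimates can
change abruptly between samples — one of the behaviors the synergy
estimator is designed to avoid.

## Personalization utilities

* `fmax_from_acsa()`: peak isometric force as anatomical cross-sectional
  area × the maximum muscle stress of 100 N/cm². Applied to the bundled
  29-MTU reduced-set table (`trunk_mtu_table()`), it reproduces the table's
  force column exactly.
* `distribute_group_acsa()`: splits a muscle group's total ACSA over the
  member MTUs of the reduced set in proportion to their generic ACSAs.
* `tune_fiber_lengths()`: rescales optimal fiber and tendon slack length
  jointly — holding $\ell_T^s/(\ell_T^s + \ell_M^o)$ fixed — so the peak
  normalized fiber length over a gait trial equals a target, 0.95 by
  default ("slightly less than 1"), for near-optimal force generation. The
  solution is closed-form because lengths enter linearly.
* `reduce_mtu_set()`: optimization-based muscle-set reduction — nonnegative
  least squares for reduced-set peak forces such that, over many random
  poses at full activation, the reduced set reproduces the original set's
  joint moments.

## Evaluation

`moment_rmse()` gives the per-DoF RMSE between estimated and
inverse-dynamics moments. Activation estimates are compared to measured
excitations with `emd_sweep()`: an electromechanical delay from a 100–165
ms grid (5 ms steps, spanning reported erector spinae delays) is applied to
the excitation curve, and the delay with the highest Pearson correlation is
reported; r > 0.7 is flagged as strong. Delays are applied as *circular*
shifts — gait is periodic, and circular shifting avoids edge-padding
choices — with fractional-sample shifts by linear interpolation. The
interpolation matters: at 101 samples per cycle one sample is ~11 ms, so
nearest-sample rounding would alias neighboring 5 ms grid points onto the
same shift and make the sweep's argmax ambiguous. Amplitude scaling of
excitations is irrelevant to Pearson correlation, so no scaling is applied
beyond display.

## The synthetic generator, and what passing tests mean

`make_dataset()` builds gait datasets with known ground truth: bundled
reduced-set MTU parameters with smooth synthetic geometry (moment arms
within ±0.08 m, both agonists and antagonists per DoF; normalized fiber
lengths within [0.7, 1.0]); per-side synergy activations as wrapped-
Gaussian bumps with stereotyped timing and small cycle-to-cycle jitter; leg
activations $W_\mathrm{leg} H$ with per-synergy anchor muscles; trunk truth
$W_\mathrm{trunk} H$ with heads of one group sharing weights; moments from
the same muscle model; truncated-Gaussian activation noise (sd 0.05) and
Gaussian moment noise (sd 1 Nm, below the 5 Nm allowance so tracking stays
the dominant signal); and a surrogate "measured" excitation — the true ES
group-mean activation circularly advanced by a known 120 ms delay,
rescaled to a different amplitude (exercising the scale-invariance of the
correlation metric) and noised.

Two generator choices deserve emphasis because they define what the
recovery tests can and cannot show.

**Effort-consistent ground truth.** Three lumbosacral moment components
cannot pin down six muscle groups per side: during any synergy's active
window the group allocation has twice as many unknowns as equations, so
arbitrary agonist–antagonist co-contraction is invisible to net joint
moments and *no* moment-driven method can recover it. Ground-truth weights
drawn freely at random are therefore unrecoverable in principle. The
generator instead keeps the self-consistent effort-optimal recruitment
implied by a raw random draw: it iterates an allowance-weighted nonnegative
least-squares moment fit (Lawson–Hanson NNLS, an algorithm and code path
independent of the estimator's bounded quasi-Newton solver) to a fixed
point. This mirrors the motor-control premise already embedded in the
estimator's activation-minimization term and in static optimization.
Consequently, passing recovery tests demonstrates that the full pipeline —
synergy extraction, normalization, convex weight optimization, constraint
handling — correctly inverts moment data generated by effort-consistent
recruitment; it does **not** demonstrate that stabilizing co-contraction in
real subjects would be recovered, because it cannot be, by this or any
moment-tracking method.

**Identifiable synergy structure.** Non-negative factorizations are not
unique in general. The generator keeps the validation problem identifiable:
synergy bumps are spread over the cycle with spacing that keeps them
distinguishable, and each synergy dominates one anchor leg muscle, as gait
synergies tend to do. Real EMG gives no such guarantee — factorization
non-uniqueness on real data is a known limitation of the approach — so the
tests validate the machinery, not uniqueness on arbitrary data.

Other deliberately simple choices: noise is additive (truncated on
activations, plain Gaussian on moments); cycle durations are ~1.1 s with
small variation; the generator does not attempt marker, ground-reaction or
forward-dynamics realism.

## Numerical choices

* Normalized fiber lengths are clamped to [0.01, 1.8]; clamp counts are
  reported via an attribute rather than silently discarded.
* Active force–length width $\gamma = 0.45$, a common Hill-model
  convention; configurable.
* NMF: convergence at 1e-6 relative error change, at most 2000 iterations,
  denominators guarded by 1e-12; negative inputs and out-of-range $k$ are
  argument errors; an all-zero synergy activation is a degenerate-synergy
  error (it cannot be max-normalized).
* L-BFGS-B: `factr = 1e5`, up to 3000 iterations; augmented-Lagrangian
  outer loop up to 30 rounds with penalty escalation ×5.
* Delay-sweep ties break toward the smallest delay; the delay grid must lie
  within the cycle.
* Storage files are written with 15 significant digits so read/write
  round-trips hold to 1e-12; cycle segmentation uses half-open intervals
  $[t_i, t_{i+1})$ so no sample is counted twice (the final closing strike
  keeps its sample when it ends the trial).
* Gait cycles are resampled to 101 points (0–100% in 1% steps), the
  gait-analysis convention.
* EMG conditioning defaults (30–300 Hz band-pass, rectification, 6 Hz
  envelope, trial-maximum normalization) are package conventions — they are
  not tied to any particular laboratory's chain and are fully configurable.

## Problem sizes used by the tests and the acceptance script

Recovery checks run the full study shape: 29 trunk MTUs per side, 3 DoFs,
k = 7 synergies per side extracted from 15 leg channels, 10 cycles of 101
samples, with 10 NMF restarts per extraction. The synergy-count trend uses
10 single-cycle datasets at the same shape, k = 5…8. Oracle-equivalence
checks use tiny instances (2–6 muscles, 1–3 DoFs, a handful of samples)
where exhaustive grids, triple-loop summations and 10⁴-point random
searches are exact or near-exact references. These sizes are the package's
own validation choices and run in about two minutes altogether.

## Known limitations

* Synergy activations are assumed shared between ipsilateral leg and trunk
  muscles; the package estimates under that assumption and cannot test it.
* Rigid tendon, no force–velocity, no activation dynamics and no pennation:
  force is affine in activation by design, which both matches the
  optimization structure and limits fidelity during rapid contractions.
* Moments about only the three lumbosacral DoFs are tracked; thoracic or
  lower-extremity DoFs are out of scope.
* Whether a real recruitment strategy is effort-optimal is an assumption,
  not a finding; see the generator discussion above.
* Single-channel validation: with real data the correlation metric can be
  computed only for muscles that were actually measured (erector spinae in
  the motivating study).
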