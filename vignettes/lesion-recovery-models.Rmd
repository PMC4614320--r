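---
title: "Modeling spatio-temporal network damage and recovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling spatio-temporal network damage and recovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`lesionsim` studies a clinical paradox with two deliberately different
network models: damage of a given total size can cause *less* disability when
it arrives slowly than when it arrives at once. Both simulators remove a
contiguous block of `m` nodes according to a lesion schedule - all at once
(immediate), one node every IRT time units (gradual), or `n_p` packages of
`m/n_p` nodes every IRT units (resection) - and record a disability trace.
The primary outcome is the **maximum amount of disability (MAoD)**: the
largest disability value after damage onset. The package's headline,
statistically tested claim is that mean MAoD is nonincreasing in the
inter-removal time (IRT) in both models.

## The three-layer model

Three rings of `N` binary nodes (input, middle, output). Node `j` of one ring
feeds the inclusive modular range `j - floor(n/2) .. j + floor(n/2)` of the
next, i.e. `n + 1` connections. The phrase "`n` neighboring nodes" and the
printed index range conflict by one; we implement the range, which is the
more precise statement, and expose `n_effective = n + 1`.

Middle nodes are stochastic sigmoid units: with summed input
`X_i = sum_j W[i,j] input_j`, node `i` fires with probability
`1/(1 + exp(-beta (X_i - theta_ml)))`. Output nodes are deterministic
Heaviside units with threshold `theta_output` (a sum exactly at threshold
fires; results are insensitive to this tie convention for continuous
weights). Disability is the Hamming distance `H` between actual and desired
output. While `H > 0`, weights update by the Hebbian-like rule

    delta_w = eta (a s_post s_pre - b s_post - c s_pre),

clipped to `[w_min, w_max]`; with the reference constants
(`a = 1.5`, `b = c = 0.5`) this is `+eta/2` for coactive pairs, `-eta/2` when
exactly one unit is active, 0 otherwise. Reference values (defaults of
`three_layer_params()`): `N = 500`, `n = 100`, `theta_ml = theta_output =
5.54`, `beta = 0.25`, `w_max = 10.3`, `w_min = 0`, `eta0 = 0.01`, `H0 = 5`.

The learning rate is either fixed at `eta0` or *modified*: constant up to
disability `H0`, then the quarter-ellipse
`eta0 sqrt(1 - ((H - H0)/(Hc - H0))^2)`, reaching 0 at the critical
disability `Hc`. A modified-eta network whose damage pushes `H` past `Hc`
can never relearn; `Hc` is case-dependent and therefore required
configuration whenever `mode = "modified"`.

### Design choices the model description leaves open

**Teacher signal.** The Hebbian rule alone cannot steer the output toward a
target, so for the middle-to-output update the postsynaptic state is the
*desired* output bit (clamped Hebbian); the input-to-middle update uses
actual activities. This is the minimal supervised reading of "weights change
as long as a difference exists between desired and actual output".

**Update gating (per output bit).** We gate the middle-to-output update per
output bit: only rows whose output currently disagrees with the desired bit
update. The alternative - updating every connection whenever total `H > 0` -
was implemented and rejected on empirical grounds: because some output
always errs during early training, the teacher-clamped weights of already
correct outputs keep growing for essentially the whole pre-lesion phase,
inflating their drive to 5-6x threshold. Such a network shrugs off any
lesion with `m <= n` (a surviving handful of near-`w_max` afferents still
exceeds threshold), which contradicts the lesion phenomenology both models
are built to exhibit. With per-bit gating each output freezes at a
just-trained margin (~1.3x threshold) and lesion size and speed matter.
`run$gating = "global"` restores the alternative.

**Initial weights.** Not specified by the model description. Uniform on
`[w_min, w_scale]` with `w_scale = 2 theta / (n_effective x presynaptic
rate)`, so the expected summed drive of a fresh unit sits at its threshold.
Uniform on the full `[w_min, w_max]` range (about 47x larger drive) was
rejected for the same reason as global gating: it saturates the middle layer
and trains into a lesion-insensitive state. `init_weight_max` overrides the
automatic scale.

**Learning-rate policy during pre-lesion training.** The modified policy
engages at damage onset; the pre-lesion phase always trains at the fixed
base rate `eta0`. From random initial weights the starting disability is
about `N/2`, far above any case's `Hc`, so a modified policy applied from
step 0 could never learn at all - yet the model is explicitly given "enough
time to learn" before the lesion. Damage-dependent plasticity is a statement
about injury, not about initial learning.

**Other conventions.** One input/desired pattern pair per run, each drawn
with exactly `active_fraction x N` (default 50%) active nodes; layers update
synchronously input -> middle -> output once per step; ring indices are
0-based and all neighborhoods wrap modulo `N`; pre-lesion training lasts a
fixed 1000 steps (the damage onset used throughout) rather than stopping at
`H = 0`, which keeps runtime bounded and matches the time axes of the
reference experiments; the middle layer draws its `N` uniform deviates every
step even for dead nodes, so paired runs (different schedules or policies,
same seed) share identical random streams - this is what makes the
IRT-equivalence family (immediate = gradual(IRT=0) = resection(IRT=0) =
resection(n_p=1)) hold bit-exactly per seed.

## The homeostasis model

A recurrent ring of `n_nodes = 100` stochastic binary neurons, 80%
excitatory, with synapse *counts* as connectivity: `C[i,j]` synapses from
`j` to `i`, each contributing +1 (excitatory presynaptic neuron) or -1
(inhibitory) per spike - counts-as-weights is the minimal reading of a model
that plasticizes "the number of connections". Input is
`X_i = sum_j sign_j C[i,j] s_j + Poisson(lambda)`; firing probability is the
same sigmoid with `theta = 500`, `beta = 0.002`. Every `morph_period = 100`
activity steps a *morphological step* moves each neuron toward the
homeostatic target rate 0.5: with `Fbar_i` the mean firing probability over
the last `window = 1000` activity steps,

    delta_I = nu (Fbar_i - 0.5) I_i

on the input side (`I_i` = in-degree, `nu = 0.005`) and analogously on the
output side. Above-target neurons lose synapses, below-target neurons form
new ones with partners drawn from a Gaussian ring-distance kernel. Network
disability is the population variance, across alive neurons, of `Fbar_i` -
zero exactly at homeostasis, at most 0.25.

### Design choices

**Fractional changes.** `nu Fbar I` is usually well below 1, so signed
drives accumulate in per-neuron residuals and only integer parts are
realized - synapse counts stay integers and the target state (`Fbar = 0.5`
everywhere) is an exact fixed point.

**Role of `p_del`.** The parameter list includes a deletion probability that
the model equations never use. We give it the natural role: each synapse the
homeostatic rule marks for removal enters a pending pool and is actually
deleted with probability `p_del` per morphological step (victims drawn
proportionally to current counts), making structural decay stochastic and
gradual; `p_del = 1` recovers deterministic removal. Formation is immediate.

**Initial in-degree 940.** Chosen so that unsigned expected drive at the
target rate, `0.5 x 940 + 30`, equals the threshold 500. With signed
synapses and an 80/20 excitatory mix the signed fixed point actually sits
near in-degree 1570, so during burn-in the homeostatic rule itself grows the
network the rest of the way; from this initialization the mean absolute rate
deviation `|Fbar - 0.5|` falls below 0.01 within ~1200 morphological steps,
well inside the 2700-step burn-in used before any lesion.

**Kernel scale.** `kernel_sigma = 10` ring units: new partners are drawn
mostly within +/-20 neighbors, local on a ring of 100 yet wide enough that a
reference lesion (10 adjacent neurons) does not fully disconnect anyone.

**Dead neurons** lose all synapses, are barred from future synapse
formation, and are excluded from the disability variance - otherwise the
variance could never recover after a lesion, contradicting the recovery this
model is meant to show. Removing an already-dead node is a warning-level
no-op.

**Recovery timescale.** Linearizing the homeostatic loop around its fixed
point gives a recovery time constant of roughly `4 / (2 nu beta (theta -
lambda))`, about 425 morphological steps at the reference values - recovery
is therefore much slower than the inter-removal times studied (0-20), and
the IRT effect on peak disability comes from the window-averaging of `Fbar`
plus partial recovery during the removal sequence, not from full healing
between removals. This makes the homeostasis ordering intrinsically noisier
than the three-layer one, which is why the paired ordering experiments use
more replicate seeds (30) than the minimum and, for the homeostasis model,
average each seed's peak over independent post-burn-in branches
(`n_branches`) of the same lesioned network.

## Experiments, statistics, and reproducibility

`run_three_layer_trial()` and `run_homeostasis_trial()` produce disability
traces; `maod()` reduces a trace to its post-onset maximum;
`gradual_grid()`, `resection_grid()`, and `homeostasis_irt_sweep()` run
(size x IRT), (packages x IRT), and (IRT) designs with per-cell,
per-replicate seeds derived from one master seed (`derive_seed()`), so grids
are reproducible and independent of enumeration order. Orderings are tested
with one-sided exact sign tests over paired seeds (`maod_sign_test()`), not
by eye. The homeostasis sweep computes each seed's burn-in once and branches
per IRT from a snapshot of state and RNG; with a single branch per cell this
is bit-identical to running each trial from scratch (asserted in the test
suite), and with several branches the cell value is the mean peak over
independent realizations, a lower-variance estimator of the same quantity.

The default experiment scale is `N = 100`, `n = 20` for the three-layer
model with `m = 16` and IRT 0 vs 50 (the full `N = 500` reference scale is
available via `run$scale = "full"`), and the reference 100-neuron model with
`m = 10` and IRT 0 vs 20 for homeostasis. Recovery phases default to
`4 x removal span + 2000` steps (three-layer) and a 300-morphological-step
post-lesion window (homeostasis), placing the MAoD well inside the simulated
window. The package's own test suite runs these designs end to end; the
burn-in convergence check (mean `|Fbar - 0.5| < 0.05` in at least 80% of
seeds) and both IRT orderings are recomputed from scratch by
`scripts/acceptance.R`.

## What the simulations do and do not show

All inputs are generated by the simulators themselves (random binary
patterns, Poisson drive); there is no external data. The generators emulate
localized, contiguous lesions in small homogeneous ring networks with a
single stored association (three-layer) or a single homeostatic set point
(recurrent). They do not model spatially scattered damage, partial damage
(weight attenuation), conduction delays, continuous-valued neurons, vacant
synaptic elements, or cell-death cascades; passing tests support the
size-vs-speed trade-off as a robust property of these two architectures, not
a quantitative prediction for biological tissue. Known limitations worth
keeping in mind: the three-layer MAoD at the desk scale is an integer count
on a 100-node output ring, so paired comparisons can tie at small effect
sizes; and with signed synapses, gradually removing a mixed
excitatory/inhibitory block can transiently overshoot the net immediate
shock (the partial sums of a signed sequence can exceed their total), which
occasionally reverses the per-seed homeostasis ordering even though the mean
ordering is stable.
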