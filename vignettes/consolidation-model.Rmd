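---
title: "The stochastic consolidation model: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The stochastic consolidation model: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The model

`memconsol` simulates lifelong memory in a sparse Hopfield-type attractor
network of `N` binary neurons. Memories are uncorrelated binary patterns
with a fraction `f` of active units (throughout we use `f = 0.01`), stored
as weighted Hebbian outer products in a symmetric synaptic matrix. The
weight of memory `l`, its *efficacy* `A_l(t)`, obeys

    dA_l/dt = -A_l / tau + b * R_l(t),      A_l(l) = 1,

a competition between exponential synaptic decay (time constant `tau`,
measured in units of the interval between the arrival of two consecutive
memories) and stochastic rehearsals: `R_l` is an inhomogeneous Poisson
process with rate

    r_l(t) = lambda * F(A_l(t) / A_c(t)),

where `lambda` is the maximal rehearsal rate and each event increments the
efficacy by `b < 1` (a rehearsal is weaker than the initial encoding).
Retrieval is limited by the crosstalk of all stored memories, the
interference noise `Delta^2 = (f/N) * sum_n A_n^2`. A memory is a stable
attractor only while its efficacy exceeds the critical efficacy
`A_c = a(f) * Delta`; the normalized basin-of-attraction size `F` of a
memory depends only on `A/A_c`. Because `Delta` couples every memory to
all others, rehearsals are self-amplifying (a large basin attracts more
rehearsals) and collectively self-limiting (consolidation raises the
noise floor for everyone). These two facts produce the model's central
phenomenon: retrieval probability decays smoothly with memory age, with a
tail time constant `tau_c` that can exceed the synaptic decay time by
orders of magnitude.

# The mean-field stability analysis

The basin function is derived, not assumed. One synchronous update of the
network maps the overlap `m` between the state and a memory of
efficacy-to-noise ratio `r = A/Delta` to

    G(m, r) = H(H^{-1}(f (1 - m)) - r m) - f (1 - m),

with `H` the upper Gaussian tail. `overlap_fixed_points()` locates the
fixed points of `G` by a dense scan (2000 points) for sign changes of
`G(m) - m` followed by bisection to 1e-10. Above a critical ratio `a(f)`
a pair of nonzero fixed points exists — the retrieval attractor `M_s` and
the basin boundary `M_us` — and the basin size is approximated by
`M_s - M_us`. `critical_ratio()` bisects on the existence of that pair;
at `f = 0.01` it gives `a(f) = 4.6496`, within 0.4% of the closed-form
approximation `1.44 * sqrt(2 * log(1.9 / f))`.

Two numerical choices deserve comment.

* **The overlap at criticality.** With exact root-finding the two fixed
  points merge at `m = 0.769` for `f = 0.01`. Iterative schemes that
  classify a fixed point by convergence of the map dynamics suffer
  critical slowing just above the saddle-node and typically report
  criticality slightly late, where the stable root has already risen to
  ~0.84 (at a ratio of 4.70 the roots are 0.688 and 0.839). We report the
  exact tangency.
* **Normalization of `F`.** `build_basin_table()` tabulates raw basin
  widths on 400 log-spaced ratios `A/A_c` in `[1, 50]` and normalizes by
  the width at the upper end, so that `sup F = 1` and `lambda` is a true
  maximal rate. `F(x) = 0` for `x <= 1` (the width vanishes at the
  saddle-node), and at large ratios the basin boundary merges with the
  destabilized zero state, so the raw width saturates at 1.

**Sensitivity of the equilibrium to `F`.** The consolidation time is set
by the probability of a long rehearsal-free gap while an efficacy decays
from the fixed point `A_fp ~ b*lambda*tau` down to `A_c` — an integral of
`lambda * F` over the escape corridor that typically amounts to 5–10
expected events. The equilibrium observables therefore depend
*exponentially* on percent-level features of `F` between `x = 1` and
`x ~ 3`: a 5% change of `F` in the corridor moves `tau_c` by tens of
percent and shifts the self-consistent equilibrium (`A_c`, capacity,
consolidation probability) with it. Independently produced tabulations of
`F` (different grids, iteration schemes, interpolants) should be expected
to disagree at this level; this is the model's intrinsic conditioning,
not a numerical defect. It matters most in the strong-rehearsal regime
(`lambda*tau = 10`, `b = 0.25`), where the package's slow tail constant
is in the 50–65 `tau` range while coarser basin tabulations can land near
35–40 `tau`.

# The stochastic simulator

`run_simulation()` integrates the coupled efficacy equations with a
compiled core. Per step of length `dt = 0.05 / lambda`:

1. every efficacy is multiplied by the exact factor `exp(-dt/tau)`
   (no Euler bias in runs of hundreds of `tau`);
2. `Delta` and `A_c` are recomputed from the decayed state;
3. each memory with `A >= A_c` receives an increment `b` with probability
   `lambda * F(A/A_c) * dt` (Poisson thinning; the per-step probability
   is at most 0.05 by the choice of `dt`, so the thinning bias is
   negligible);
4. one new memory with efficacy drawn from the configured
   initial-efficacy distribution (constant 1 by default) is inserted at
   each integer time.

Before the first memory arrives `Delta = 0` and `A/A_c` is undefined; the
rate is then `lambda` (the limit `F -> 1`). Memories with
`A < 1e-6 * A_c` and age `> 10 tau` are dropped from the active set —
their interference contribution is below the double-precision noise floor
of `Delta^2` — but they remain in every observable's denominator (see
below). All randomness flows through R's RNG; realization `r` of a
configuration runs under `set.seed(seed + r - 1)`, so runs are bitwise
reproducible.

**Equilibrium detection.** The interference noise, averaged over
realizations and over consecutive windows of `10 tau`, must change by
less than 2% between windows. Detection uses `Delta` rather than `A_c`
because `A_c` can be momentarily infinite in fixed-threshold mode.

**The forgetting curve** is the fraction of memories of a given age with
`A > A_c`, pooled over post-equilibrium snapshots. Two estimator details
matter more than they look:

* the bin *population* is computed analytically (exactly one arrival per
  unit time), so memories dropped from the active set still count as
  unretrievable — otherwise old-age bins contain only survivors and the
  tail flattens artificially;
* each snapshot contributes only ages younger than `t - t_eq`, i.e. only
  memories born after equilibration. Earlier cohorts consolidated under a
  much lower `A_c` and would inflate the old-age bins.

**Consolidation probability** `p_c` is the fraction of (post-equilibrium,
non-censored) memories whose efficacy ever exceeds
`A_c + 0.8 * (A_fp - A_c)`; "reaching the fixed point" is ill-defined
under fluctuations, so we require crossing most of the gap. The
consolidation time `tau_c` is the exponential tail constant of the curve
(ages beyond `5 tau`), or the slow component of a double-exponential fit
when a sizable fraction of memories fails to consolidate
(`b*lambda*tau` well above 1). Tail fits exclude bins with fewer than 5
retrieval events (they sit at the sampling noise floor and masquerade as
an extra slow component) and use the younger half of the observed age
range: the oldest clean cohorts were born right at the detected
equilibration time and carry a residual upward bias from the last
percents of `A_c` drift.

# The full network

`network_forgetting_curve()` and `measure_basin_size()` validate the
mean-field machinery on the actual binary network: patterns are drawn,
the connectivity matrix is assembled from centered outer products, and
retrieval runs synchronous updates in which the `round(f N)` neurons with
the largest local fields activate (a global inhibition constraint). The
dynamics stops when the state repeats with period 1 or 2 — synchronous
symmetric dynamics can two-cycle, in which case the cycle state with the
larger overlap is scored. A memory is retrievable if the final overlap is
at least 0.85; basins are measured by flipping `k` active units off and
`k` inactive units on, increasing `k` until recovery fails, normalized by
`2 f N`.

Retrieval experiments use *count-matched* patterns (exactly `round(f N)`
active units). With i.i.d. Bernoulli(`f`) patterns the active count
fluctuates by `sqrt(N f (1-f))` while the dynamics clamps the activation
at `round(f N)`; a pattern with too many or too few active units then has
an overlap ceiling below the 0.85 cut for purely combinatorial reasons
(at `f N = 20`, roughly 40% of Bernoulli patterns are structurally
unretrievable). Pattern-generation statistics are still tested, and
available, in the Bernoulli form.

Finite size shifts the retrieval threshold: at `N = 2000` (`f N = 20`) a
memory needs `A ~ 1.35 A_c` to survive the field fluctuations, so the
pure-forgetting step sits ~0.3 `tau` before the analytic catastrophic age
while remaining sharp (width < 0.3 `tau`).

# Structural perturbations

Perturbation experiments run the simulator in *fixed-threshold* mode: the
firing threshold `theta` is held constant (0.36 by default, near the
capacity optimum of the unperturbed network) and the critical efficacy is
looked up in a tabulated map `A_c(Delta; theta)` built by
`critical_efficacy_fixed_threshold()`. The map solves, per noise level,
for the minimal efficacy whose overlap dynamics at fixed `theta`
converges to a stable retrieval (overlap >= 0.85, population activity
comparable to `f`); it has a floor `~ theta/(1-f)` at small noise — the
encoding must cross the threshold — rises weakly with `Delta`, and jumps
to infinity at a critical noise where the quiescent state destabilizes
(`H(theta/Delta) > f`, runaway background activation). Stability of this
map need not be monotone in the efficacy near the catastrophe (a strong
memory activates all of its pattern neurons and can tip the background
into runaway while a weaker one sits marginally below); a noise level
with an empty or fragmented stable set is treated as supercritical.

Because the map is capped below the catastrophe, strong-rehearsal
configurations self-organize at the edge: the noise rides just below the
critical value and occasionally crosses it for an integration step,
during which no memory is an attractor. These blockade instants are an
artifact of the binary cliff in the tabulated map; retrieval observables
(forgetting curves, capacities) therefore condition on snapshots with a
finite `A_c`, treating blockades as measurement gaps.

Two perturbations are modeled:

* **Additive synaptic noise** (diffusion coefficient `D`, from
  `t_onset`): adds `f * tau * D^2 / (2N) * (1 - exp(-2 (t-t_onset)/tau))`
  to `Delta^2`, integrated exactly per step; a finite window
  (`t_offset`) lets the accumulated noise decay at rate `2/tau`
  afterwards. The transient `A_c` rise interrupts consolidation of
  memories encoded near the onset, producing the characteristic
  non-monotonic, temporally graded deficit; memories encoded later
  consolidate under the new equilibrium and recover toward control.
* **Synaptic dilution** (silenced fraction `p`): scales every retrieval
  signal by `1-p` and the noise by `sqrt(1-p)` (in the full network, a
  symmetric Bernoulli mask — synapse death severs both directions of the
  symmetric pair). Since `A_c` depends weakly on `Delta` below the
  catastrophe, the signal loss dominates and retrievability drops across
  the post-onset age range, recovering only slowly. Old, fully
  consolidated memories sit far above `A_c` in this implementation and
  show little retrograde deficit — a weaker retrograde effect than the
  graded one the fixed-threshold analysis can produce when the
  equilibrium sits closer to the critical efficacy (see the sensitivity
  note above).

`optimize_threshold()` grid-searches `theta` under common random numbers;
lowering the threshold lowers both the `A_c` floor (helping diluted
memories clear it) and the critical noise (hurting capacity), which is
the tradeoff behind threshold adaptation after injury.

# Heterogeneous decay times

With per-synapse decay times, a memory's efficacy becomes a profile over
the decay-time distribution: bins of the distribution decay at their own
rates while a single rehearsal process per memory adds `b` to every bin.
Retrieval and rehearsal are driven by the mean efficacy across the
distribution; the interference uses the second moment. Decay times are
Pareto: density `alpha * tau0^-(alpha+1)` on `[1, Inf)`, scaled so the
minimal decay time is `tau_min` (20 in the reference setup), with the
maximal rate calibrated so that the mean number of rehearsals per
*empirical mean* decay time equals `R0`.

The distribution is discretized into 50 bins: 90% of the probability in
equal-probability bins, the remaining 10% in tail bins of geometrically
halving mass (each represented by the decay rate at its median). Pure
equal-probability binning would cap the slowest represented time scale at
the `1 - 1/(2K)` quantile (~430 time units for `alpha = 1.5`,
`tau_min = 20`) and impose an artificial exponential cutoff on retention
exactly where the power-law tail lives; the refined tail reaches beyond
`tau ~ 1e4` at the same bin count, and the binned decay kernel agrees
between 50 and 100 bins to better than 2% over ages 10–2000. For
`alpha <= 1.2` the quantiles are truncated at the 99.9th percentile (the
raw mean diverges at `alpha <= 1`); the truncation is recorded in the
output. Intermediate exponents (`1 < alpha < 1.8`) produce retention
curves that a power law fits better than an exponential, with a log-log
slope near 1 at `alpha = 1.5`; large exponents recover the exponential
tail of the homogeneous model. Fits use ages in
`[2 tau_min, 0.5 * max observed age]` for both models.

# Study conditions and problem sizes

The package's reference conditions are `N = 8000`, `f = 0.01`,
`tau = 160`, with `(lambda*tau, b) = (5, 0.3)` for the exponential-tail
regime and `(10, 0.25)` for the double-exponential regime; run length
`400 tau` with 10–12 realizations for headline numbers (the test suite
uses these, plus reduced sizes — `tau = 20`, `N = 2000`, 2–4
realizations — for mechanical checks). The pure-forgetting reference uses
`tau = 2240` at `N = 8000`, rescaled to `N = 2000` by keeping
`tau/tau_0(N)` fixed. These sizes give per-bin forgetting-curve samples
of several hundred thousand at young ages and standard errors well below
the assertion tolerances.

# Known limitations

* The rehearsal process is imposed through the basin-size rate law, not
  generated by a neural mechanism (attractor hopping, sleep replay);
  only the rate's proportionality to basin size is modeled.
* Equilibrium observables inherit the exponential sensitivity to the
  basin function discussed above; cross-implementation comparisons of
  `tau_c`, equilibrium `A_c` and capacity should allow for tens of
  percent in the strong-rehearsal regime.
* The fixed-threshold analysis treats the supercritical region as a hard
  blockade; in a finite network over-activation develops gradually.
* Synapses are unbounded and sign-free (no Dale's law); decay-time
  heterogeneity is independent per synapse with a single Pareto family.
* The full-network simulations are memory-bound by the `N x N` dense
  connectivity; curves at `N = 8000` with hundreds of `tau` of stored
  history are mean-field only.
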