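---
title: "Models of systems memory consolidation in parallel synaptic pathways"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models of systems memory consolidation in parallel synaptic pathways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppcons)
```

## The scientific problem

Declarative memories initially depend on the hippocampus and are later
expressed by neocortical circuits.  `ppcons` implements a mechanistic
account of this transfer: wherever a brain region receives the same
information through an *indirect, multisynaptic* pathway (slow, holding
the original memory) and a *direct, monosynaptic* shortcut (fast,
plastic), spike timing-dependent plasticity (STDP) in the shortcut will
copy the input-output association from the indirect pathway into the
direct one.  The indirect pathway's extra transmission delay means its
postsynaptic effect *follows* the shortcut's input by a few
milliseconds — exactly the causal, pre-before-post timing that STDP
potentiates.  The indirect pathway thereby acts as a supervisor for the
shortcut.

The package builds this idea up across four scales, each a module with
its own simulation and readouts:

1. **Kernel theory** (`coefficient_A()`, `coefficient_B()`,
   `fixed_point_weights()`): a rate-based analysis of the STDP dynamics.
2. **Single spiking cell** (`run_copy_experiment()`,
   `run_spatial_replay_experiment()`): a conductance-based
   integrate-and-fire neuron copying weight patterns between its two
   input pathways.
3. **Multi-stage hippocampal circuit** (`run_watermaze()`): a rate
   network storing object-place associations, consolidating them
   through two nested shortcuts, decoded with a Bayesian place decoder
   and probed with simulated lesions.
4. **Hierarchical cascade and its linear theory** (`trace_memory()`,
   `integrate_overlaps()`): iterating the motif across a cortical
   hierarchy yields a travelling "memory wave" and power-law
   forgetting.

## The drift-coefficient theory

For a linear neuron $y = W^\top x + V^\top x'(t-D)$ with separable input
statistics — autocorrelation $f(\tau)$ within the direct pathway and
cross-correlation $g(\tau)$ between pathways — the STDP weight drift is

$$\frac{1}{\eta}\,\dot W = A\,\langle xx^\top\rangle W +
  B\,\langle xx'^\top\rangle V, \qquad
  A = \int L(\tau)f(\tau)\,d\tau, \quad
  B = \int L(\tau)\,g(\tau - D)\,d\tau,$$

where $L(\tau)$ is the learning window ($\tau > 0$: pre before post).
`A < 0` makes the dynamics stable; `B > 0` makes the fixed point

$$W^* = -\tfrac{B}{A}\,\langle xx^\top\rangle^{-1}\langle
xx'^\top\rangle V$$

a positive-gain linear regression of the indirect drive — consolidation
is literally the least-squares copy of the old memory that the shortcut
can express.  `classify_regime()` names the three regimes
(consolidating, stable-eroding, unstable).

Numerical choices: the $A$ integral is folded onto the half line,
$A = \int_0^\infty [L(\tau)+L(-\tau)]\,f(\tau)\,d\tau$ (valid because a
stationary autocorrelation is symmetric), so the antisymmetric-window
cancellation is pointwise-exact instead of a difference of two large
quadratures.  Adaptive quadrature covers 25 window time constants
(exponential tails < 1e-10) with interior break points at the window
discontinuity and the delay.  Dirac-delta kernels are treated
symbolically: the integral collapses to `amplitude * L(D)`, avoiding any
discretization of the discontinuity at zero lag.  The zero-lag pair is
assigned to the depression branch throughout the package ($\Delta t = 0$
depresses), and $\beta = -B/A$ is reported as `NA` when $A = 0$ (the
pure supervised-learning limit), not as infinity.

## The spiking weight-copy experiment

A single conductance-based leaky integrate-and-fire cell (membrane time
constant 20 ms, threshold -54 mV, reset -60 mV, refractory 1.75 ms,
synaptic decay 5 ms, forward Euler at 0.1 ms) receives the *same*
Poisson spike trains (10 spikes/s per afferent) through two synapse
populations, the indirect one delayed by 5 ms.  The teacher population
has fixed weights drawn from the bimodal steady-state distribution of
additive STDP (half exponential with mean `0.05 g_max`, half `g_max`
minus such a draw); the learner starts from an independent bimodal draw.
Additive STDP (LTD/LTP amplitude ratio 1.05, time constant 20 ms,
all-to-all pairing via exponential traces, hard bounds $[0, g_{max}]$)
then raises the correlation between learner and teacher weights when
the teacher is the *delayed* pathway, and fails (the correlation goes
negative: active deletion) when the roles are swapped.

Desk scale: the test profile uses 200 afferents per pathway with
`g_max` five times the published value (preserving the total synaptic
drive of 1000 afferents), learning rate `eta = 0.01` (2x published) and
1600 s of simulated time.  These were fixed once, before the acceptance
thresholds were evaluated, by requiring visible convergence of the
forward direction; the directional *asymmetry* is robust to all of
them.  The published duration for the copy figure is not stated; the
trajectory, not a fixed endpoint, is the readout.

The spatial-replay experiment reuses the same cell as a point-neuron
surrogate for a morphologically detailed pyramidal cell (the
compartmental machinery — dendritic calcium spikes gating plasticity —
is out of scope; somatic spikes gate STDP instead, so this is a
functional, not biophysical, reproduction).  2500 place afferents
(25 cm fields) teach 500 grid afferents (2-6 fields across a 2.5 m
track) a single place field.  At replay speed (20x physical motion,
5 m/s) field crossings last ~50 ms, matched to the STDP window, and the
grid-input tuning converges to the theoretical reference
(`theory_tuning()`: the superposition of all grid fields active at the
target).  At physical speed (0.25 m/s) crossings last seconds, the
cross-correlation is far wider than the window, and consolidation
fails.  The plastic pathway is initialized at the *bimodal* steady
state: a uniform initialization is not drift-free (chance pairings
diffuse mid-range weights upward and masquerade as tuning gain at slow
speeds).

## The multi-stage hippocampal model

Four layers (entorhinal cortex EC, dentate/CA3, CA1, subiculum), each
split into N place-coding and N object-coding cells.  EC place cells
carry a grid code (three plane waves 60 degrees apart, spacings spanning
2-6 periods, random orientation and phase); dentate/CA3 place cells
carry Gaussian place fields (width 0.1) on a regular grid in the unit
square.  Object codes are place codes evaluated at a random "object
position" and permuted within the population, giving matched rate
statistics without a 2-D manifold constraint.  The indirect pathway
(`V_SC`) and the CA1-to-subiculum relay carry scaled identity blocks
(1/4 and 1/2); associations are imprinted into the object-to-place
block of `V_SC` by a normalized Hebbian outer product
(`imprint_association()`, strength `lambda = 0.6`, largest column sum
rescaled to 1 — the inner normalization equalizes memories, the outer
one bounds the weights and causes interference-driven forgetting).
Nightly consolidation activates random positions and objects (5 ms
steps, 150 s per night at the published scale) and updates the two
perforant-path shortcut matrices with the trace-based STDP rule; the
subiculum shortcut learns at half the CA1 rate, which is what extends
its memory lifetime.

Memory strength is read out by Bayesian decoding: the place-population
response to an object cue is compared against the place-code templates
with a Gaussian likelihood and a flat prior.  Two printed variants of
the exponent exist (with and without a population-size factor); with
standardized responses the squared distance itself grows with N, so the
factor-N variant caps the log-likelihood range at $2/\sigma^2 \approx
0.09$ at *any* N and decodes nothing.  The implementation uses the
factor-free exponent, which reproduces sharp probability maps; at the
desk scale (N = 64) the noise parameter is shrunk to
$4.8\sqrt{64/256} = 2.4$ so the likelihood concentration $N/\sigma^2$
matches the published setting.

The watermaze protocol (`run_watermaze()`): equilibrate the SC with 125
imprints and the shortcuts with 10 cycles, imprint the tracked platform
association on day 0 (platform at a quadrant center, the standard task
geometry), then every day store one new interfering association (in a
remapped environment) and consolidate for one night.  Probes decode the
tracked object through SC, PP_CA1 and PP_SUB; the pathway with the
highest posterior peak is selected (ties to the later pathway) and its
quadrant mass is mixed with 70% uniform exploration.  A uniform
posterior gives exactly 25% per quadrant; full mass in the target
quadrant gives 47.5%.  Lesions zero the PP_CA1 matrix and freeze its
plasticity, either before acquisition or after the probe on a chosen
day.

Desk scaling (test profile): N = 64 cells, 16 objects, 15 s nights.
STDP amplitudes are raised 4x — not the full 10x night-length ratio,
because the systematic drift per night scales as $A\,T_c$ while the
stochastic weight churn scales as $A\sqrt{T_c}$, so no single factor
preserves both; 4x is the regime where one night still consolidates to
decodability and churn does not dominate shortcut retention.  Pathway
lifetimes in this world are roughly 6 days (SC), 18 days (PP_CA1) and
beyond 32 days (PP_SUB), so lifetime-ordering experiments run 32 cycles
with the lesion on day 16.

The arena is the unit square (the published field centers sit on a
regular grid there); quadrants are its four equal sub-squares with
boundaries going to the lower/left.  Place-to-object decoding is not
implemented (not needed for the watermaze task).

## The hierarchical cascade

`trace_memory()` surrounds a single hippocampal matrix (row-normalized
binary, imprinted daily with `lambda = 0.5`) with L shortcut matrices
whose STDP amplitudes fall geometrically (`0.4 w_max q^{i-1}`,
`q = 0.5`).  Fresh rectified-Gaussian activity (mean 10, sd 5 spikes/s)
enters the outermost layer each 5 ms step; every connection delays one
step; inward copies are exact, outward stages mix one half shortcut
with one half relayed activity.  The Pearson correlation of each
shortcut with the day-0 reference pattern traces the memory: levels
peak sequentially (the memory wave), and the max over levels decays
approximately as a power law, which `compare_decay_models()` tests
against an exponential alternative by OLS on log-log versus semi-log
axes over the days where the signal exceeds three times the 1/N
readout noise floor.

Desk scaling: amplitudes keep their published values at every night
length — the per-step weight kick is already a quarter of `w_max` at
level 1, so raising amplitudes for short nights rails the $[0,w_{max}]$
bounds and replaces the signal with churn (verified at 2x, 4x and 10x,
including with finer integration steps).  A 15 s night then transfers
so little that the shortcut signal sits at the noise floor; the
acceptance analysis therefore uses 60 s nights (the smallest with a
measurable level ladder) and 40 cycles (the signal is below the floor
after ~day 16).  A green wave/power-law test at this scale establishes
the mechanism's orderings, not the published forgetting-curve span of
years, which needs the full 1000-cycle, N = 256 world.

## The linear overlap theory

`integrate_overlaps()` abstracts the cascade into a linear ODE for the
overlaps $O_i(t)$ between each shortcut matrix and the initially stored
memory: the hippocampal channel decays exponentially
($\tau_{overwrite} = 1$ day by default — it only sets the time unit;
the published figure does not state it), and each shortcut integrates
the channels below it with weights $c_{ij}$ ($c_{i0} = \alpha^i$,
$c_{ij} = \alpha^{i-j}(1-\alpha)$, summing to one) and kernel values
$A(D_{ij}) = \exp(-2D(i-j)/\tau_{STDP})$, scaled by learning rates
$\eta_i = 2^{-i}$.  One modelling decision matters: extrapolating the
kernel formula to the diagonal ($i = j \Rightarrow A = 1$) would make
every overlap monotonically non-decreasing (a lower-triangular system
with positive diagonal and non-negative drive can only grow), which
contradicts the rise-then-decay behaviour this theory exists to
explain.  The zero-lag pre/post pair lies on the *depression* branch of
the learning window — the same $\Delta t = 0$ convention used by the
spiking rule — so the diagonal coupling is $-1$ (`self_kernel`,
configurable).  With it, each $O_i$ rises and decays, peak times grow
geometrically, and the max envelope is an approximate power law: its
local log-log slope (sliding window of one scallop period) varies by
less than 0.5 over the central two decades, versus ~100 for the purely
exponential hippocampal channel.  The integrator is an in-package
adaptive Dormand-Prince RK45 (tolerances 1e-10/1e-12); the hippocampal
channel is cross-checked against its closed form at 1e-8 and the full
solution against a matrix-exponential oracle in the tests.  The default
six-decade time grid spans 0.1 to 1e5 days so the central two decades
sit inside the self-similar ladder (the first decade holds the
non-power-law rise of $O_1$).

## Synthetic data: what it emulates and what it does not

All inputs are generated in-package from seeds: homogeneous Poisson
trains (exact exponential intervals, not binned thinning), delayed
copies, back-and-forth track sweeps with field-gated Poisson firing
(alternating direction; the published protocol does not state the
alternation rule), uniform positions, and row-normalized binary memory
matrices (all-zero rows redrawn — their normalization is undefined).
The generators reproduce the *statistical* conditions the models
assume: stationary rates, exact cross-pathway spike copies, independent
nightly activity.  They do not emulate theta modulation, behavioural
pauses, non-stationary rates or realistic trajectory statistics, so a
green test establishes the consolidation mechanism under its stated
assumptions, not robustness to those realisms.  One master seed drives
every stream; sub-seeds are derived deterministically per purpose, so
every experiment is bit-reproducible.

## Known limitations

* The compartmental pyramidal-cell model behind the original
  spatial-replay figure (active dendrites, calcium-spike-gated
  plasticity) is out of scope; the point-neuron surrogate reproduces the
  speed dependence functionally.
* Desk-scale worlds compress lifetimes; quantitative values (days,
  correlations) are specific to each profile and only orderings and
  regime boundaries are claimed.
* The lesion-before-acquisition experiment: with the perforant path to
  CA1 silenced, the model still consolidates into the subiculum
  shortcut through the intact SC -> CA1 -> SUB relay, so late probes
  are *not* at chance in this implementation (see the acceptance test
  for the measured behaviour).  Making late probes fail would require
  an additional assumption — e.g. that subicular consolidation is gated
  by CA1 shortcut activity — that the printed model equations do not
  contain.
* Quadrant occupancy assumes probe-time exploration mirrors the decoded
  posterior (70/30 explore/exploit); no trajectory-level swimming is
  simulated.
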