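---
title: "Modelling HCN-channel shunting in layer V pyramidal cells with ihcable"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling HCN-channel shunting in layer V pyramidal cells with ihcable}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Thick-tufted layer V pyramidal cells (L5PCs) express HCN ("Ih") channels at
high and distally increasing density along their apical dendrite.  Because
the Ih reversal potential (about -45 to -30 mV) sits *above* rest but *below*
spike threshold, the current can either excite (it depolarizes the resting
membrane) or inhibit (its open conductance shunts synaptic charge, and the
depolarized rest inactivates other channels).  `ihcable` is a compact
compartmental simulator built to dissect this dichotomy: it implements the
cable equation on branched morphologies, the published kinetics of two Ih
variants and of the low-voltage-activated (LVA, T-type) calcium channel, an
apical calcium-channel "hot zone", neuromodulation operators that shift the
Ih voltage dependence, and the experiment protocols (threshold searches,
distance sweeps, distributed-synapse grids with nonparametric statistics)
needed to quantify when Ih helps and when it hinders action-potential (AP)
initiation.

The central mechanism the package reproduces: with Ih intact, the distal
apical membrane rests depolarized, which *inactivates* the LVA channels of
the hot zone (their inactivation gate `h` is low).  Blocking Ih
hyperpolarizes the dendrite, de-inactivates the LVA channels, and thereby
*lowers* the threshold for calcium-spike-mediated APs from distal stimuli --
even though the same block *raises* the threshold for proximal and somatic
stimuli.  The threshold-versus-distance curves of the intact and Ih-blocked
cell therefore cross near the hot zone; removing the hot zone removes the
crossing.

## Model and numerics

**Cable equation.**  The morphology is split into frustum compartments
(default max length 20 um; soma one iso-potential sphere, consistent with
somatic point stimulation).  Voltage is advanced by backward Euler with a
Hines-ordered tree solve (exact one-sweep elimination), gating variables by
exact exponential (Rush-Larsen) updates at the start-of-step voltage, and
channel currents are linearized within each implicit step.  This fixed-step
implicit scheme replaces the adaptive integrator used in the original
studies: it is unconditionally stable, bitwise deterministic, and its
adequacy is shown by convergence tests (halving `dt` or the spatial step
moves responses by < 0.5%; the passive solver matches RC and finite-cable
closed forms to 0.1%/1%).  Default `dt` is 0.025 ms with a settle phase
(default 0.5-1 s) before stimuli; gates are additionally initialized to
their steady state at `v_init`.

A deliberate consequence of the discretization used by the stimulus
protocols: a square pulse is "on" for `t` in `[onset, onset + duration)`,
so a pulse ending exactly at `t_stop` is off in the final step.  Protocol
code that reads steady-state values therefore keeps stimuli on past the
sampling time.

**Gate tables.**  The engine consumes per-gate lookup tables (steady state
and per-step decay factor on a 0.05 mV grid from -150 to +110 mV) that are
built in R by the *same* rate functions the unit tests verify against
closed-form oracles -- the compiled core contains no second copy of any
kinetic equation.  Per-compartment neuromodulation enters as a voltage
offset into the table lookup plus a time-constant scale factor.

**Channel kinetics.**  Both published Ih variants are implemented: a
rate-based form (alpha/beta with a removable singularity at the alpha
offset, reversal -45 mV) and a sigmoid form with a two-exponential time
constant and `q10` temperature adjustment (reversal -33 mV).  The LVA
channel has gates `m^2 h` with sigmoid steady states (half points -40 and
-90 mV) and sigmoid-bump time constants.  One sign convention required a
decision: the printed inactivation steady state, read literally, would
*increase* with depolarization, contradicting both the physiology of
inactivation and the reported resting values of `h` (about 0.05 with Ih
versus 0.5 without).  We implement `h` as decreasing in V, which preserves
the printed half point `h_inf(-90) = 0.5`.  The calcium reversal is a
dynamic Nernst potential fed by a single-shell first-order calcium pool
(shell depth 0.1 um, decay 80 ms, rest 1e-4 mM), advanced by exact
exponential steps.

**Neuromodulation.**  cAMP-linked modulation is modelled as a shift of the
Ih voltage dependence: every voltage argument is replaced by `V - dv`, so
positive `dv` (cAMP-enhancing) moves the activation curve toward
depolarized potentials and opens more channels at rest.  By default the
shift applies to the time-constant curve as well as the steady state
(`shift_tau = TRUE`), since the biophysical interpretation is a shifted
voltage sensor; the steady-state-only behaviour is switchable because the
source text pins down only the half-activation point.  An independent
`tau_scale` models fast HCN1-like kinetics (e.g. 0.25 for 4x faster).
Only Ih may be targeted; the operators are exactly invertible
(`+dv` then `-dv` restores the curves to 1e-12).

**Stimuli.**  Square current pulses; peak-normalized alpha conductances
(`g_max` at `t = onset + tau`; normalization is our choice -- it makes
threshold conductances comparable across time constants); single-exponential
AMPA/GABA-A synapses (`tau` 2 ms, reversals 0/-80 mV); and two-state NMDA
receptors (rise 2 ms, decay 100 ms, activation rate 2 kHz, magnesium block
`1/(1 + Mg exp(-0.062 V)/3.57)` with `[Mg] = 1 mM` by default -- the
concentration is never stated in the source and is exposed in the synapse
constructor).  Seeded populations place `N` synapses uniformly *per unit
dendritic length* (captions say "uniformly distributed along" the dendrite)
within a closed distance interval; glutamatergic populations are AMPA+NMDA
pairs sharing site and conductance, GABAergic populations draw activation
times uniformly from a +/-25 ms window.

## The synthetic stated world

No reconstructed morphology ships with the package; `make_ball_and_tuft()`
generates a stylized thick-tufted cell and `make_scenario()` dresses it
with the reduced mechanism set.  The defaults *are* the stated world of the
acceptance tests and were chosen once, as follows:

* **Geometry** -- soma 23 um sphere; apical trunk 1300 um tapering 4 to
  1.2 um (so the largest protocol distance, 1300 um, lies on the trunk)
  plus two 300 um tuft branches and two mid-trunk obliques; five 250 um
  basal dendrites.  These are round numbers in the range of published L5PC
  reconstructions.
* **Passive** -- `cm` 1 uF/cm^2, `Ra` 100 ohm cm, leak 3.38e-5 S/cm^2 to
  -85 mV, with the apical leak doubled as a spine correction.  With Ih this
  rests the soma near -75 mV; blocking Ih hyperpolarizes to -85 mV,
  matching the direction and magnitude of the published voltage traces.
* **Ih profile** -- 2e-4 S/cm^2 at soma/basal, growing exponentially along
  the apical dendrite with length constant 400 um (about 25x at 1300 um),
  emulating the published exponential distal enrichment whose exact
  coefficients are model-specific configuration, not package constants.
* **LVA hot zone** -- apical baseline 187 uS/cm^2 with a x100 multiplier on
  the closed interval 685-885 um (the published removal baseline and
  multiplier), or the alternative absolute style (300 mS/cm^2 inside
  585-985 um, 3 mS/cm^2 elsewhere).
* **Spike mechanism** -- a generic two-gate Na (m^3 h) / one-gate K (n^4)
  pair confined to the soma (2.0 / 0.6 S/cm^2).  The reduced set
  (leak + Ih + LVA + calcium pool + somatic Na/K) suffices because channel
  screens in the source show the other currents do not carry the
  qualitative phenomenon.

With these defaults the stylized cell reproduces, at desk scale: the
threshold crossover near the hot zone (around 600 um here versus 650-700 um
in the full models), the monotone control <= blocked ordering once the hot
zone is removed, resting LVA inactivation of 0.06 versus 0.31 at 800 um
(full models: 0.05 versus 0.49), the calcium-spike burst regime for strong
distal inputs, and all the neuromodulation directions.  What a green test
does *not* establish: quantitative threshold magnitudes of the published
full models (those require their complete channel sets and reconstructed
morphologies, available from the public model repository), basal/tuft
morphometric statistics, spine-level effects, or frequency-resonance
behaviour -- all out of scope.

## Protocols and statistics

* `fi_curve()` -- somatic DC from 200 ms; frequency = spikes in
  `[500, 16000]` ms / 15.5 s (the window shrinks with `t_stop` for
  desk-scale runs); AUC by trapezoid over the supplied amplitudes (the
  source does not state its amplitude range, so reproduction configs must
  mirror the published axes).
* `find_threshold()` -- doubling bracket from a seed value (0.1 nA or
  1e-3 nS) up to a cap (default 300 nA / 1 nS per synapse), then bisection
  to 1% relative width; "no AP up to cap" is a flagged result, not an
  error, mirroring the grey cells of the published grids.
* `distance_sweep()` -- thickest-branch site selection at each distance;
  short pulses default to 0.2 ms (the methods value) with a documented 2 ms
  preset (the figure value) used by the crossover acceptance test; local
  peak voltages above 100 mV are flagged unphysiological.
* `grid_experiment()` -- upper-triangular `(x1, x2)` cells; per repeat, one
  seeded placement shared across variants; per cell a two-sided
  Mann-Whitney U test, Bonferroni-corrected by the *recomputed* number of
  tested cells (66 for the standard 200-1300 um grid; 198 for three-way
  comparisons).  The U statistic uses midranks; p-values come from exact
  enumeration when `min(n) <= 8` without ties, else a tie- and
  continuity-corrected normal approximation.  Two-sidedness is our reading
  of the published "p < 0.05/66" framing.
* `combined_basal_apical()` -- adds basal drive to every run: 80% of the
  control whole-basal threshold conductance (glutamatergic) or 0.2 nS
  GABAergic synapses with per-repeat jittered times.  The published 18 pS
  figure value is not taken as normative; the 80%-of-threshold rule is.
* `split_neuromod_experiment()` -- independent `dv` on `[0, 500]` um and
  `(500, tip]` of the apical dendrite.

Desk-scale tests shrink the sampling (tens of synapses, `n_samp` 2-5, 1-2
grid cells) purely for runtime; the protocol code paths are identical to
full-scale runs, and every stochastic choice is reproducible from the
recorded seeds.

## Known limitations

Single-cell only (no networks or extracellular fields); no adaptive time
stepping; no stochastic gating, short-term plasticity or receptor
desensitization; the non-printed channels of the full published models are
supported only through the generic gate plug-in with user-supplied
parameters; axon initial-segment specialization and 3D geometry effects are
not modelled.
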