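---
title: "Model and methods: apical and basal dendritic contributions to orientation tuning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

Layer 2/3 pyramidal neurons of mouse primary visual cortex receive
feedforward, visually driven input mostly onto their basal dendrites and
feedback input onto the apical tuft. Individual synapses are themselves
orientation-tuned, so the neuron's somatic orientation preference emerges
from how the two dendritic trees integrate thousands of weakly tuned,
sparsely firing inputs. `apicobasal` implements a conductance-based
multicompartment model of such a neuron together with the protocol suite
used to attribute somatic spikes to one tree or the other: dendritic
nonlinearity profiling, orientation tuning under dendritic disparity,
just-in-time ionic and synaptic interventions with per-spike attribution,
and morphometry-linked attenuation analyses.

## The electrical model

The morphology is a branched tree of cylindrical dendritic segments plus an
isopotential equivalent-area spherical soma. Membrane potential follows the
cable equation; each compartment carries a leak plus seven voltage- (and
calcium-) gated conductances: fast sodium (Na), delayed-rectifier potassium
(Kdr), muscarinic potassium (Km), transient A-type potassium (KA),
low-threshold (CaT) and high-voltage-activated (CaHVA) calcium, and
calcium-dependent potassium (KCa), with a first-order submembrane calcium
pool (shell depth 0.1 um, pump time constant 200 ms, resting concentration
0.1 uM).

Passive parameters: `C_m` = 1 uF/cm^2, `R_a` = 100 Ohm cm, `g_leak` =
1/17300 S/cm^2 and `e_leak` = -79 mV, giving a membrane time constant of
17.3 ms and a passive resting potential of -79 mV, the documented operating
point of the modelled cell. Reversal potentials default to +60 mV (Na),
-80 mV (K) and +140 mV (Ca); all are config-exposed.

### Channel densities

Densities are region- and geometry-dependent (`default_density_rules()`),
in mS/cm^2 as published for this cell type:

| channel | soma | apical | basal |
|---|---|---|---|
| Na | 0.505 | 0.303 | 0.303 |
| Kdr | 0.05 | 1.5e-3 | 1.5e-3 |
| Km | 2.8e-3 | 1.27e-3 | 1.27e-3 |
| KA | 5.4 | 108 if d <= 0.8 um else 10.8 | same |
| CaT | 0.03 | 0.029 sin(0.009x + 0.88) for x <= 260 um, else 0.012 | 0.03 + 6e-5 x |
| CaHVA | 0.05e-3 | 0.049e-3 sin(0.009x + 0.88) for x <= 260 um, else 0.02e-3 | 0.05e-3 + 1e-7 x |
| KCa | 2.1e-3 | 2.1e-3 | 2.1e-3 |

with x the path distance from the soma (um, evaluated at each compartment
midpoint) and d the segment diameter. Two numerical points deserve note:

* **The apical calcium sinusoid is clamped at zero.** The printed
  expression `0.029 sin(0.009x + 0.88)` becomes negative for x in roughly
  (249, 260] um; a conductance density cannot be negative, so the rule
  returns 0 there. The two pieces therefore do not meet at the 260 um
  cut-over: the density jumps from 0 to 0.012 mS/cm^2. The discontinuity is
  recorded by a test and left as printed rather than smoothed.
* **Per-channel unit interpretation in the simulator.** Read uniformly as
  mS/cm^2, the Na/Kdr/Km rows are physically incompatible with the cell's
  documented behaviour: a somatic Na density of 0.505 mS/cm^2 yields a
  maximum sodium current (~50 uA/cm^2) smaller than the conductance load of
  the attached dendritic tree, so no action potential could ever fire —
  contradicting the 66.1 mV spike amplitude and the dendritic sodium spikes
  this model is known for. Conversely a KA density of 108 S/cm^2 would be
  physically absurd. The self-consistent reading is that the Na/Kdr/Km rows
  are in the simulator-native S/cm^2 convention while the remaining rows
  are mS/cm^2. `conductance_at()` always returns the numbers as printed;
  `build_system()` applies the per-channel factor set
  (`default_sim_scale()`: 1000 for Na/Kdr/Km, 1 otherwise), which is
  attached to the rule set and can be overridden.

### Channel kinetics

The gating kinetics are the package's default mechanism set: standard-form
Boltzmann steady states with bell-shaped voltage-dependent time constants,
integrated with the exact exponential update
`x <- x_inf + (x - x_inf) exp(-dt/tau)` (unconditionally stable; gates stay
in [0, 1] for any dt). The set was tuned once so that, with the densities
above, the model reproduces its documented operating points: spike
initiation near -45 mV, resting potential -79 mV, and a small-amplitude
action potential that peaks above 0 mV (so an upward crossing of 0 mV with
a 3 ms refractory period cleanly detects somatic spikes).

| gate | midpoint (mV) | slope (mV) | tau (ms) |
|---|---|---|---|
| Na m (power 3) | -30 | 5 | 0.04 + 0.2/cosh((V+30)/12) |
| Na h | -48 | -6 | 0.25 + 4/cosh((V+48)/10) |
| Kdr n | -25 | 9 | 0.5 + 3/cosh((V+25)/20) |
| Km n | -35 | 9 | 10 + 30/cosh((V+35)/20) |
| KA m (power 4) | -10 | 19 | 0.2 + 1/cosh((V+10)/30) |
| KA h | -56 | -6 | 5 + 20/cosh((V+56)/15) |

CaT follows the classic low-threshold transient form (activation midpoint
-57 mV, inactivation -81 mV), CaHVA the classic high-voltage-activated
rate forms, and KCa a first-order calcium-dependent gate (forward rate
0.01 per ms per mM of calcium, backward 0.02 per ms). All kinetics are
inspectable at any voltage via `channel_kinetics(v)`.

## Synaptic drive

Synapses are conductance-based double exponentials
`g(t) = g_max N (exp(-t/tau2) - exp(-t/tau1))`, normalised so the peak is
`g_max`: AMPA 0.84 nS (0.1/2.5 ms), NMDA 1.15 nS (2/30 ms), GABA_A 1.25 nS
(0.2/1.4 ms). NMDA is additionally gated by the standard sigmoidal
magnesium block `1/(1 + [Mg]/3.57 exp(-0.062 V))` with [Mg] = 1 mM. Each
excitatory site is a co-located AMPA + NMDA pair sharing one presynaptic
train.

Drive statistics follow the modelled experiment: 75% of synaptic sites are
background-driven (homogeneous Poisson at 0.11 Hz for the whole run) and
25% stimulus-driven (Poisson at an orientation-tuned rate, zero before the
500 ms stimulus onset). The tuned rate is a circular Gaussian of the
difference between the synapse's orientation preference and the stimulus,
peaking at 0.3 Hz with a 30 degree width (the functional form is the
package's choice — the modelled experiment states only that rates are
orientation dependent — and the width is recorded in every result).
Per-synapse preferences are wrapped Gaussians (sigma 30 degrees) with
tree-specific means: both trees at 0 degrees normally; under *dendritic
disparity* the basal mean is offset by D degrees. Apical stimulus-driven
synapses carry a 10 ms transmission delay, reflecting the later arrival of
feedback input.

Distribution models allocate sites across trees: *biologically plausible*
(60% basal / 40% apical, for both stimulus- and background-driven),
*inverted* (40/60), *even* (50/50), and an *even background* variant (60/40
stimulus but 50/50 background excitation; inhibition 46.5/46.5 with a 7%
somatic share). Inhibitory (GABA_A) sites are background-driven only.

## The synthetic cell and its calibration

`generate_synthetic_morphology()` builds the study's standing test cell:
five unbranched basal stems (80-150 um long, 0.9-1.4 um diameter) sprouting
from a 12 um soma, and a 150 um apical trunk (2 um) carrying a depth-3
binary tuft of 60 um segments tapering from 1.1 um to ~0.8 um. The layout
mirrors the proximal-basal / distal-apical split of the real cell: all
basal path distances are below ~180 um while most tuft segments lie beyond
it (the deepest tuft level falls below the 0.8 um A-type diameter switch,
so that rule is exercised).

Because the synthetic cell is much shorter than a real L2/3 arbor
(~1.6 mm vs several mm of dendrite), realistic *per-micron* synapse
densities would underdrive it. The default total site count (~4.8 sites/um,
i.e. ~7500 sites) and the inhibitory share of background sites (25%) were
therefore calibrated once, by scanning for the regime in which every trial
neuron fires at the preferred orientation (a few Hz) and stays near-silent
at the orthogonal one, and then frozen. The synthetic cell fires faster at
its preferred orientation (~5-10 Hz) than the reproduced cell (1.55 Hz);
the qualitative structure — sparse background firing, tuned stimulus
response, apically dominated spike generation — is the point of the
fixture, not the absolute rate. What passing tests on this cell do *not*
show: agreement with the original morphology's printed per-segment means
(those require the deposited reconstruction), realistic tuft branching
statistics, or in-vivo-like input correlations (all trains are independent
Poisson processes).

## Numerics

The branched cable plus membrane system is advanced by a first-order
implicit (backward Euler) step: gates advance first by their exact
exponential updates at the current voltage, synaptic and ionic conductances
are then frozen for the step, and the resulting linear tree system is
solved exactly by Hines elimination (compartments ordered parent-before-
child). This is unconditionally stable at the 0.1 ms step used throughout
(10 kHz recording); time-step refinement shifts somatic spike times by less
than 0.1 ms, and grid refinement (halving the 0.1 lambda compartment limit)
changes steady-state responses by under 1%. The NMDA magnesium block is
evaluated at the previous step's voltage, keeping the step linear.
Calcium influx uses the post-step voltage and an exact exponential update
of the pump/decay relaxation.

Interventions scale a parameter — a tree's sodium density, or the
conductance of its stimulus-driven AMPA/NMDA synapses — for every step
whose end time falls inside the closed window `[start, end]`; at 0.1 ms
resolution the open/closed distinction is one sample. Gating states keep
evolving during the window, so restoring the parameter restores the
baseline trajectory exactly when nothing else differed. Intervention
re-runs are truncated shortly after the spike under test (the survival
window plus 6 ms); inputs up to the truncation point are identical, so the
truncation cannot change the outcome.

## Protocol choices

* **Paired-pulse profiling (`i3p`)**: n synapses at the segment midpoint
  fire two synchronous volleys 20 ms apart (50 Hz); every other compartment
  is passive, the window is 700 ms with the first volley at 100 ms, and
  thresholds are judged on the first volley's response. The sodium phase
  (AMPA only) detects regenerative events as max dV/dt >= 10 mV/ms and
  peak >= 20 mV above baseline; the NMDA phase adds NMDA, disables the
  target segment's sodium channels (isolating the slower regenerativity)
  and requires the depolarisation to stay above the 20 mV gate for >=
  10 ms. Both criteria are config-exposed and echoed with every result,
  since the original detection rule is not published. NRLE — the maximum
  over n of actual(n)/(n x actual(1)) — is computed from the sodium-phase
  curve.
* **Tuning**: each trial is an independent neuron instantiation (fresh
  placements, preferences, trains); rate = spikes in [onset, end] / 2 s.
  Tuning width is the sigma of a wrapped-Gaussian fit (not HWHM), fitted by
  a coarse (preferred, sigma) grid with linear baseline/amplitude solves,
  then refined; sigma is constrained to [3, 100] degrees. OSI uses the
  fitted curve at the preferred and orthogonal orientations. Per-trial
  metrics are reported next to the mean-curve fit, and adequacy means OSI
  >= 0.2 and width <= 80 degrees in at least 80% of trials.
* **Interventions**: ionic = sodium nullification from 3 ms before to 1 ms
  after the pre-recorded spike; synaptic = 50% stimulus-weight reduction
  from 30 ms before to 10 ms after. A spike survives if the re-run fires
  within +/- 5 ms of the baseline time (the matching window is the
  package's choice). Survival patterns classify spikes as apically driven,
  basally driven, cooperative, or independent — a partition, so the four
  percentages always sum to 100.
* **Attenuation**: the EPSP probe calibrates a synchronous local input by
  bisection to a 20 +/- 1 mV local peak on a passive membrane and reports
  local minus somatic peak (a difference in mV, not a ratio); the spike
  probe keeps the target segment active and drives it at twice its sodium
  threshold. Comparisons across trees use covariate-normalised responses
  (response / length, diameter, volume, or electrotonic length) with
  unpaired two-sample t-tests; paired designs use the dependent t-test;
  outlier exclusion is an explicit, recorded argument.
* **Ablation**: removing the apical tree raises input resistance; the
  homeostatic variant scales the remaining excitatory weights uniformly
  (bisection) until the preferred-orientation rate matches the intact cell
  within 10%, then re-measures tuning.
* **Sensitivity**: whole-run apical sodium scaling at 1.0 / 0.95 / 0.90
  re-runs the stimulated model and reports spike counts (non-increasing in
  the scale) and, optionally, the attribution classes.

Reduced presets (`reduced_experiment_presets()`) pin the problem sizes used
by the test suite and the results script: 3 orientations x 2 trials for the
smoke tuning run, disparities {0, 40, 90} for the disparity sweep, and a
10-12 spike cap per trial for the intervention runs. These sizes were
chosen so each preset completes in minutes on one CPU while still
exercising the full pipeline.

## Known limitations

* The deposited reconstruction and mechanism files of the original cell
  are separate downloads; without them the package runs on its synthetic
  cell and its default kinetics, which reproduce the qualitative biology
  but not the printed per-segment means (tuning width 44 degrees, basal
  sodium threshold 12.3 synapses, distal-apical attenuation 17.6 mV, case
  percentages, and the Table of electrophysiological properties). A user
  with the converted SWC can pass it to `load_swc()` and run every
  protocol unchanged.
* Inhibition is background-driven and unpatterned; there is no short-term
  plasticity, no interneuron subtypes, and no receptive-field structure.
* The disparity experiment's linear expectation is computed from the
  actually sampled synapse preferences with equal weights (all stimulus
  synapses share one peak conductance); conductance-weighted expectations
  would differ only under heterogeneous weights.
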