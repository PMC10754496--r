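# apicobasal

Pyramidal neurons in layer 2/3 of mouse primary visual cortex receive
feedforward, visually driven input mostly on their **basal** dendrites and
feedback input on their **apical** tuft. Both trees integrate thousands of
sparsely firing, individually orientation-tuned synapses, and both shape
the neuron's somatic orientation tuning — but through different mechanisms.
`apicobasal` is a self-contained R implementation of a conductance-based
multicompartment model of such a neuron, together with the in-silico
protocol suite used to dissect each tree's contribution:

- **Morphology**: SWC reading/writing, per-segment morphometrics
  (length, diameter, volume, path distance, branch order, electrotonic
  length L/λ with λ = √(R_m·d / 4R_a)), plus a synthetic L2/3-like cell
  generator for fully reproducible experiments.
- **Biophysics**: seven voltage/calcium-gated conductances (Na, Kdr, Km,
  KA, CaT, CaHVA, KCa) with region-, distance- and diameter-dependent
  density rules (e.g. apical CaT `0.029·sin(0.009x + 0.88)` mS/cm² up to
  260 µm, basal `0.03 + 6·10⁻⁵·x`; A-type 108 vs 10.8 mS/cm² across the
  0.8 µm diameter switch).
- **Synaptic drive**: double-exponential AMPA/NMDA/GABA_A conductances
  (Mg²⁺-blocked NMDA), orientation-tuned Poisson trains (background
  0.11 Hz, stimulus-driven up to 0.3 Hz after a 500 ms onset), and
  tree-wise allocation models (60/40 basal/apical "biologically
  plausible", even, inverted, ...).
- **Engine**: implicit (backward-Euler) integration of the branched cable
  with exact Hines solves and exact exponential gate updates, 10 kHz
  recording, current clamps, and just-in-time parameter interventions
  (time-windowed scaling of a tree's sodium density or stimulus-driven
  synaptic weights).
- **Protocols & analysis**: paired-pulse dendritic input-output curves
  with sodium/NMDA spike thresholds and the NRLE nonlinearity index
  (max over n of actual(n)/(n·actual(1))); orientation tuning curves with
  wrapped-Gaussian fits (OSI = (R_pref − R_orth)/(R_pref + R_orth), width
  = fitted σ); dendritic-disparity sweeps against the linear Euler-formula
  expectation ½·arg(Σ w_j e^{2iθ_j}); per-spike attribution (apically
  driven / basally driven / cooperative / independent); EPSP and spike
  attenuation probes; apical ablation with homeostatic compensation; and
  apical sodium sensitivity sweeps.

Results are tibbles; fitted objects support `tidy()`/`glance()`; tuning,
input-output and intervention results have `autoplot()` methods.

## Worked example

```r
library(apicobasal)

m <- generate_synthetic_morphology(seed = 1)
m
#> <ab_morphology> 21 segments (15 apical, 5 basal), total dendritic length 1573 um

# dendritic nonlinearity of one basal stem
prof <- i3p(m, segment_id = 2, n_values = c(1, seq(2, 60, 2)), duration = 400)
prof
#> <ab_i3p> segment 2: sodium threshold 12, NMDA threshold 16, NRLE 3.218

# orientation tuning (3 trial neurons x 6 orientations)
tun <- tuning_experiment(m, orientations = seq(0, 150, by = 30),
                         n_trials = 3, seed = 1)
tun$fit
#> <ab_tuning_fit> preferred 0.8 deg, width 23.7 deg, OSI 0.957 (R_pref 7.83 Hz, R_orth 0.17 Hz)

# attribute each somatic spike by just-in-time sodium nullification
ivn <- intervention_experiment(m, kind = "ionic", n_trials = 3, seed = 1,
                               max_spikes_per_trial = 8)
ivn
#> <ab_intervention> ionic, 24 baseline spikes
#>   label           mean_pct sem_pct
#> 1 apically_driven    95.8     4.17
#> 2 basally_driven      0       0
#> 3 cooperative         0       0
#> 4 independent         4.17    4.17
```

Reading: a basal stem needs ~12 synchronous synapses to fire a local
sodium spike and integrates strongly supralinearly (NRLE 3.2); the model
neuron is sharply tuned to its 0° input preference (OSI 0.96); and almost
every somatic spike dies when the *apical* tree's sodium conductance is
nullified in the 4 ms around it — apical sodium spikes drive the soma,
while basal input supplies the underlying tuned depolarisation (removing
basal stimulus input abolishes tuning; see the methods vignette).

A user with the original reconstruction (converted to SWC) can substitute
`load_swc("cell.swc")` for the synthetic cell and run every protocol
unchanged.

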