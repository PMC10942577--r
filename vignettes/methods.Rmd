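---
title: "Methods: models, estimators and design choices in dentephys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in dentephys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dentephys)
```

`dentephys` implements the analysis chain used for intracellular
recordings from the dentate gyrus circuit — mossy cells (MC), granule
cells (GC) and hilar interneurons — together with a synthetic-recording
generator that provides ground truth for every stage. This vignette
documents the models, the estimators, the tunable parameters and the
design decisions, so that a user knows exactly what each number means and
what passing the test suite does and does not establish about real data.

## Units and conventions

All times are milliseconds, voltages millivolts, currents picoamperes,
conductances nanosiemens, capacitances picofarads and charges picocoulombs
(1 pA·s = 1 pC). Sample `i` (0-based) of a trace occurs at `t0 + i*dt`.
Inward currents are negative, so EPSCs recorded at depolarized holding
potentials point downward and IPSCs upward; condition-subtracted Kv7
current is positive-outward.

## The synthetic membrane

`simulate_membrane()` integrates a single-compartment model:

$$C\,\dot V = -g_L (V - E_L) - g_{Kv7}\,a\,(V - E_K)
  - g_{Na}\, m_\infty(V)\, h\,(V - E_{Na}) - g_{Kd}\, n\,(V - E_K)
  + I(t) + I_{OU}(t)$$

with first-order gates ($a$ the Kv7/M-type activation, $n$ a delayed
rectifier, $h$ slow Na inactivation) relaxing exponentially toward
Boltzmann steady states, and Ornstein–Uhlenbeck current noise
(stationary SD `noise_sigma`, correlation time 5 ms). The spike current
uses an *instantaneous* Boltzmann activation $m_\infty$ whose
hyperpolarized tail is exponential in $V$ with slope `delta_t = 2` mV —
the same onset dynamics as an exponential integrate-and-fire neuron — but
saturates at depolarized voltages. We deliberately did not use a
hard-reset integrate-and-fire model: the feature extractors measure the
full action-potential waveform (third-derivative threshold, 10–90% rise
and fall times, duration at the −10 mV crossing, peak, maximum rise
rate), which requires a continuous upstroke, peak and downstroke. The
saturating spike current plus delayed rectifier produce realistic
waveforms (amplitude ≈ 82 mV, maximum rise rate ≈ 250–350 mV/ms, duration
≈ 2.5 ms at −10 mV) while keeping the subthreshold behaviour identical to
a leaky membrane plus one Kv7-like conductance.

Default constants describe a mossy-cell-like neuron: `C = 150` pF,
`g_leak = 6.7` nS (≈ 150 MΩ), `E_leak = −65` mV, Kv7 half-activation
`−40` mV with `k = 8` mV and `tau_kv7 = 50` ms, `E_K = −90` mV. The Kv7
maximal conductance default is `g_kv7_max = 6` nS (≈ 0.04 nS/pF). This
value was calibrated once, during generator development, so that the
simulated passive properties stay in the mossy-cell range (input
resistance ≈ 140 MΩ at rest, rest ≈ −66 mV) *and* a 1.5× increase of the
conductance — the only difference between the WT and KO profiles, see
`ko_params()` — produces a clearly resolvable hypo-excitability phenotype
(fewer ramp-evoked APs, higher rheobase and rheobase charge, larger
effect of Kv7 block on input resistance) of the kind reported for mossy
cells. A conductance several-fold smaller leaves all of these contrasts
inside per-cell variability and would make the generator useless as a
recovery benchmark. All constants are overridable knobs of the generator,
not claims about any particular data set.

Integration is fixed-step RK4 on the voltage (compiled, `dt = 0.02` ms by
default, hard error if `|V|` leaves [−150, 80] mV) with exact exponential
relaxation of the gates within each step. Spike times in the ground truth
are upward crossings of 0 mV, linearly interpolated.

### What the generator does not emulate

Real mossy cells have dendrites, stochastic channel gating, synaptic
bombardment in the subthreshold range, and FMRP-dependent channel changes
beyond Kv7. Three consequences matter for interpreting results:

* The **voltage threshold** of the model barely moves when only
  `g_kv7_max` changes: a subthreshold K⁺ conductance shifts the
  Na-dependent threshold by roughly `delta_t · Δg/g_total` ≈ 0.1 mV here,
  which is smaller than realistic cell-to-cell variability. Recovery
  tests on threshold *differences* between the two genotype profiles are
  therefore expected to be statistically inconclusive in this generator,
  even though rheobase, charge and spike-count differences resolve
  clearly. A measured threshold increase in real KO tissue likely
  involves mechanisms outside a g_kv7-only model.
* Spontaneous firing at fixed subthreshold holding potentials is driven
  purely by the OU noise term; the model does not reproduce synaptically
  driven irregular firing.
* The theta–gamma stage models spike output directly as Bernoulli draws
  (below); it does not simulate the underlying EPSP-to-spike transduction.

## Voltage-clamp ramps and the Kv7 I–V curve

`simulate_vc_ramp()` returns clamp current for a command ramp: leak plus
the Kv7 current with its first-order activation lag (`tau_kv7 = 0` gives
the instantaneous Boltzmann conductance). `kv7_blocked = TRUE` removes
the Kv7 conductance, emulating a saturating XE991 application; spike and
rectifier currents are absent, as under TTX/Cd²⁺.

The analysis side (`subtract_conditions()`, `build_iv_curve()`) follows
the standard isolation-by-sensitivity design: basal − blocked isolates
the drug-sensitive current including its share of leak-free standing
current; no additional leak subtraction is applied. The quasi-steady-state
I–V curve samples every 5 mV, averaging current over a 0.01 mV command
window around each target and dividing by the cell capacitance.

One numerical point deserves emphasis: with `tau_kv7 = 50` ms and a
0.02 mV/ms ramp, the gate lags the command by about 1 mV
(`tau × rate`), which biases the measured current below the steady-state
Boltzmann curve by up to ~8–12% at subthreshold voltages — a first-order
lag error of order `tau·rate/k·(1 − a_∞)`, present in any real ramp
measurement with these kinetics. The test suite therefore checks the
instantaneous-conductance configuration against the closed form at tight
tolerance and checks the lagged configuration against the analytic lag
bound, rather than pretending the lag does not exist.

## AP feature extraction

* **Detection** (`detect_aps()`): upward crossing of −20 mV with peak
  ≥ −10 mV and ≥ 2 ms peak separation. These defaults are conservative
  and configurable; real MC APs exceed them by a wide margin.
* **Threshold** (`ap_threshold()`): the trace window (5 ms before to
  10 ms after the peak) is Savitzky–Golay smoothed (0.5 ms window, order
  3) before third-order finite differencing; the threshold is the first
  local maximum of d³V/dt³ preceding the peak that exceeds 5× the robust
  noise floor (MAD of the early window) and 5% of the pre-peak maximum.
  The relative floor handles noise-free traces where the MAD is
  degenerate; a window with no qualifying peak (e.g. a smooth sine) is
  flagged feature-undetectable rather than given a number.
* **Rheobase and charge** (`rheobase_and_charge()`): ramp current value
  at the first AP's threshold time; charge is the trapezoidal integral
  of the injected current from the depolarizing zero-crossing of the ramp
  (a hyperpolarizing onset segment is excluded) to the threshold time.
  For a linear ramp the trapezoid is exact.
* **Kinetics** (`ap_waveform_features()`): amplitude is threshold-to-peak;
  10–90% rise/fall use linear interpolation between samples; duration is
  measured between the −10 mV crossings; the maximum rise rate uses the
  raw first difference with a 0.1 ms boxcar — a positive smoothing kernel
  cannot overshoot a linear upstroke, whereas polynomial smoothing can.
* **Passive properties** (`passive_props()`): R_in = |ΔV/ΔI| with ΔV the
  difference between the mean over the last 100 ms of a ≥ 300 ms step and
  the 100 ms pre-step baseline (steady-state convention at both the
  resting and −45 mV protocols).
* **Firing patterns** (`classify_firing_pattern()`): ISI CV > 0.5 →
  stuttering-like; else maximum instantaneous rate ≥ 50 Hz with
  adaptation index (last/first ISI) < 1.3 → fast-spiking; else
  regular-spiking; fewer than 3 APs → undetermined. The three cut-offs
  are configuration defaults for qualitative classes.

## PSC event detection and statistics

`detect_events()` subtracts a 200 ms rolling-median baseline, lightly
smooths (0.5 ms boxcar) for peak finding, and accepts a candidate peak
only if it rises by at least the detection threshold (10 pA by default)
above the trough since the previously accepted peak — a prominence rule
that suppresses noise wiggles riding on decay tails, inside or after a
threshold excursion. Peaks closer than 2 ms merge to the larger one.
Amplitudes are read from the raw trace against the local pre-event
baseline (median over −10 to −2 ms); corrected amplitudes below threshold
are discarded, so every reported event satisfies |amplitude| ≥ threshold.
Multi-peak excursions are QC-flagged as overlapping rather than silently
removed, replacing manual visual verification with a reproducible flag.

The 2 ms merge window (rather than a longer one) is a deliberate
trade-off: at spontaneous rates around 10 Hz, a 5 ms merge would by
itself forfeit ~5% of true events to merging (P(ISI < 5 ms) ≈ 0.049),
putting recall at the edge of what a detector should deliver; with 2 ms
the loss is ~2% while the prominence rule still prevents double counting.

Event statistics follow the standard conventions: instantaneous frequency
1000/ISI assigned to the later event; pooled frequency histograms with
2 Hz bins normalized per cell (so normalized counts × n_cells reproduce
the pooled count exactly); right-continuous ECDFs ending at exactly 1;
rates per minute and Hz; E/I ratios on a frequency, peak or charge basis;
and drug time courses as percent of each cell's own baseline rate.

## Compound-PSC decomposition

`build_epsc_template()` averages ≥ 20 uncontaminated isolated-EPSC sweeps
(baseline: mean of the 5 ms before the stimulus). A sweep is
contaminated if its 1 ms-smoothed pre-stimulus window (50 ms) contains an
excursion beyond the detection threshold, or if the decay climbs back by
more than max(10 pA, 25% of the main peak) — an operationalization of
visual screening.

`decompose_cpsc()` scales the template to each sample of the
approximating segment — the rising-limb samples between 25% and 65% of
the excitatory peak depth, no later than 2.5 ms after the stimulus — and
averages the scaled templates into the underlying EPSC; the underlying
IPSC is the sample-wise remainder, so EPSC + IPSC = cPSC holds to machine
precision by construction. Segment samples where the template is below
5% of its peak are dropped (division-by-near-zero guard). Scaling
operates on the sweep-averaged cPSC by default; a per-sweep mode
(`per_sweep = TRUE`) is provided and agrees with the averaged mode on
synthetic data — the averaged mode is the default because scaling noisy
single-sweep segment samples divides noise by small template values.

The excitation window is the duration of the excitatory component:
from the first departure below a noise floor (3× the pre-stimulus SD,
with a 0.5%-of-peak relative guard for noise-free input) to the first
return crossing after the excitatory peak, linearly interpolated; a
missing return is right-censored at the sweep end. E/I ratios use peak
magnitudes or trapezoidal charge over stimulus → +100 ms.

## Theta–gamma analysis

`build_stim_protocol()` lays out 15 theta stimuli at 5 Hz (control) and
prepends 5 gamma stimuli at 50 Hz ending 200 ms before theta onset
(test). `ap_probability_binned()` marks a stimulus as having evoked an
AP when a detected spike falls within 50 ms after it (theta ISI is
200 ms, so windows never overlap) and reports probabilities in 1 s bins —
[0,1), [1,2), [2,3] s from theta onset, i.e. 5 stimuli per bin. The
generator (`simulate_theta_gamma()`) draws spikes Bernoulli with
`p = p_base` (control) or `p_base · (s + (1−s)(1−e^{−t/τ_rec}))` (test;
suppression factor `s`, recovery `tau_rec = 1000` ms by default,
`Inf` = constant suppression), stores the exact per-stimulus
probabilities as truth, and can render voltage traces (stereotyped APs
and EPSPs on a −70 mV baseline) so the trace-based and raster-based
estimators can be cross-checked against each other. EPSP amplitudes are
peak-minus-baseline within the response window, excluding AP-contaminated
stimuli, and are normalized position-by-position to the control train.

## Statistics

`compare_groups()` uses Welch's t by default (`var_equal = TRUE` restores
the classic Student's t) or the two-sample Kolmogorov–Smirnov test;
`anova_oneway()` is the standard one-way decomposition;
`chi_square_ratio()` is Pearson's chi-square on a groups × categories
table without continuity correction (the correction applies to 2×2
tables; firing-pattern ratios are 2×3, df = 2). Significance is taken at
p < 0.05; the summary table reports mean ± SEM with n = cells, and an
optional Benjamini–Hochberg column is available but off by default, since
the standard report applies no multiplicity adjustment.

## Cohorts, problem sizes and reproducibility

`make_cohort()` draws per-cell parameters lognormally around the group
means (CV 10% on capacitance and the four conductances), simulates every
requested protocol per cell, and is a pure function of its seed; the
pipeline (`run_pipeline()`) writes byte-identical outputs for identical
configs and seeds (default seed 0 when none is given, recorded in the
report). Cohort-level synaptic settings encode the circuit phenotype that
the membrane model cannot produce on its own: excitatory drive onto
interneurons 10 Hz (WT) vs 7 Hz (KO) against 5 Hz inhibition, evoked
IPSC components 80 vs 50 pA, and gamma-suppression factors 0.3 (WT) vs
0.7 (KO) at `p_base = 0.5` with ≥ 10 trials per cell (20 by default).
Disynaptic IPSC latency defaults to 4 ms against 2 ms for the EPSC.

The shipped tests and the acceptance script run at deliberately desk-scale
sizes — 15 cells per genotype, 4 ramp trials per cell, 30 s event traces,
25 cPSC sweeps, 200 theta–gamma trials for estimator checks and 1000
simulations for test calibration — chosen so the whole suite completes in
a few minutes on one CPU while keeping every statistical check at ≥ 3
standard errors of resolution. Passing them demonstrates parameter
recovery under the generator's assumptions (known kernels, stationary
Poisson rates, Gaussian/OU noise), not performance on real recordings
with drift, access-resistance changes, or non-stationary synaptic
activity.
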