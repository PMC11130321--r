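---
title: "Models and methods behind circuitmapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind circuitmapr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circuitmapr)
```

circuitmapr implements the quantitative core of a slice-electrophysiology
circuit-mapping workflow: feature extraction from patch-clamp recordings,
a one-dimensional classifier that separates two L5 pyramidal-neuron types
by their hyperpolarization-activated (I~h~) sag current, assembly of
layer-by-cell-type input maps from optogenetically evoked responses,
Patch-seq quality control and differential-expression gating, and laminar
axon-fluorescence profiling. Because raw recordings and sequencing runs
are not shippable, every analysis stage is paired with a seeded simulator
that generates its inputs; this vignette explains the models, the
parameters that matter, and the design decisions taken where the
procedure left room.

## Voltage-clamp step model and the I~h~ slope

The routine access-resistance test — a −10 mV, 300 ms step from a −70 mV
hold — is modeled as the sum of:

* a capacitive transient, amplitude `ΔI_transient = ΔV/Ra`, decaying with
  `τ = Ra·Cm`;
* a steady ohmic offset `ΔI_steady = ΔV/Rin`;
* optionally, a sag-current relaxation `A·(1 − e^{−t/τ_h})` measured from
  step onset; and
* a linear baseline drift plus Gaussian noise.

The sag statistic is `I_h slope = ΔI(5→265 ms)/0.260 s` in pA/s. Because
the relaxation is a single exponential, the slope implied by the
generating parameters has the closed form
`A·(e^{−5/τ_h} − e^{−265/τ_h})/0.260`, which the simulator records as
per-trace ground truth and the test suite uses as an oracle: on
noise-free traces the estimator agrees with it to better than one part in
10^3^. HCN kinetics are not biophysically constrained here — the single
exponential was chosen precisely because it admits that analytic oracle.
`tau_h_ms` defaults to 300 ms, a typical slow-HCN activation constant at
physiological temperature.

Two numerical choices matter. First, the estimator reads each endpoint
through a 2 ms boxcar, which is unbiased for linear or slowly relaxing
signals but suppresses single-sample noise. Second, the default membrane
parameters give `τ = Ra·Cm ≈ 0.3 ms`, so the capacitive transient has
decayed to numerical irrelevance at the 5 ms endpoint; with heavily
filtered pipettes (τ approaching 2 ms) the first endpoint would inherit
transient contamination and the window would need shifting.

Sign convention: the relaxation is stored positive-going so that
sag-bearing cells produce positive slopes, matching the reported positive
group values; the sag-free phenotype is represented by small baseline
drift (mean −3.1 pA/s in the calibrated cohorts), so its measured slope
scatters around zero rather than being identically zero.

## Synaptic train model and onset latencies

Light-evoked postsynaptic currents are difference-of-exponentials
waveforms (rise 1 ms, decay 15 ms by default) normalized to a programmed
peak; inward currents are negative. Trains follow the 10 Hz optogenetic
protocol with 10 pulses and 5 averaged trials. One onset latency is drawn
per pulse per train and shared across the trials of a neuron: latency is
treated as a property of the connection, with across-pulse and
across-cell scatter, while trial-to-trial jitter — much smaller in
practice — is omitted. This matters for measurement: had each trial drawn
its own latency, trial averaging would smear the rising edge and bias the
detected onset early by roughly the expected minimum of the per-trial
draws.

Onset detection works on the trial-averaged trace: the first time after
each pulse at which the current deviates, in the direction of the
requested polarity, by more than three baseline SDs and stays there for
at least 1 ms. The SD comes from the 50 ms pre-train baseline; the local
reference level is re-measured over the 2 ms before each pulse so that
the decaying tail of the previous response in a 10 Hz train cannot
register as an onset of the next. Charge is the trapezoidal integral of
the baseline-subtracted average from light onset to 400 ms after the last
pulse (configurable); charges enter the inhibition fraction
`I/(I + E)` as magnitudes. Latency-based labeling of responses as mono-
versus multisynaptic is exposed with an advisory 8 ms default boundary
but is never asserted by the pipeline, which reasons from group
statistics.

## Spiking model: regular versus burst discharge

Current-clamp recordings are generated by an exponential
integrate-and-fire neuron (τ~m~ = 15 ms, sharpness 0.3 mV, threshold
−42 mV) with a pasted stereotyped spike waveform and two spike-triggered
currents:

* an adaptation (slow AHP) current, +120 pA per spike, decaying with
  600 ms — this is what restricts a regular-spiking cell to a single
  action potential during a 500 ms near-threshold step (the 25 pA step
  granularity keeps the suprathreshold overshoot below the adaptation's
  equivalent drive); and
* in burst-capable cells, a depolarizing after-current, +280 pA per
  spike, decaying with 25 ms, which re-ignites the cell within a few
  milliseconds of the first spike and, after a single isolated spike,
  produces the depolarizing afterpotential (DAP) as a subthreshold
  rebound above the fast-AHP minimum (−58 mV).

Mode classification follows the rheobase-search convention: the first
step of the increasing sequence that elicits at least one spike is the
near-threshold step; one spike there is regular spiking, two or more are
burst spiking, and the instantaneous rate of the first pair is `1000/ISI`.

The phase-plane threshold detector scans dV/dt forward from the stimulus
onset and reports the voltage at the first sample exceeding three times
the SD of all preceding dV/dt samples (minimum 20-sample burn-in). Two
guards make this usable on sampled, noisy data: the crossing must persist
for three consecutive samples, because a single differentiated-noise
sample crosses three SDs with non-negligible probability; and the
single-spike protocol uses a moderate pulse (260 pA default, terminated
1 ms after the spike) so the passive charging dV/dt stays below the
detector's noise floor while the spike upstroke crosses it within about
a millivolt of the true initiation voltage. The brief-pulse amplitude is
exposed as a parameter rather than fixed, since the printed 2 pA value
for this protocol cannot depolarize a neuron to threshold and is treated
as a typo. With the default 0.1 mV voltage noise the detector lands
within 2 mV of the programmed threshold; it is not designed for
noise-free traces, where the running SD collapses.

## The I~h~ classifier

The classifier is a linear soft-margin support-vector machine on one
feature, solved exactly instead of through a generic QP. With decision
function `f(x) = w(x − t)` the objective is

$$J(w, t) = \tfrac{1}{2} w^2 + C \sum_i u_i \max(0,\; 1 - y_i w (x_i - t)),$$

with per-class weights `u_i = 0.5/n_{class(i)}` implementing a uniform
class prior: each class contributes equally to the loss regardless of its
size, which is the right reading of "uniform prior" for the 82-versus-65
training imbalance. For each candidate boundary `t` — every data point,
every midpoint of adjacent sorted values, and the extremes — the inner
minimization over `w` is piecewise quadratic with kinks at `w = 1/g_i`
for positive `g_i = y_i(x_i − t)` and is solved in closed form; the best
candidate is then refined by local continuous minimization, since the
soft-margin optimum need not sit exactly on a midpoint. The candidate
scan runs in compiled code; the test suite checks it against a dense
brute-force grid minimization of the same objective on small problems.
For separable data at large `C` the solution reduces to the hard-margin
midpoint of the innermost opposite-class pair. Ties at the boundary go
to the higher-slope class, deterministically. `C = 1` is the
conventional default and is exposed.

Evaluation follows the standard protocol: stratified tenfold
cross-validation repeated 20 times with fresh random divisions
(stratification is our choice — plain random divisions at n ≈ 150 would
occasionally drop a class from a training split; if that still happens
the partition is redrawn and counted), and a permutation null of 1000
label shuffles, each scored by one tenfold pass, summarized by the
empirical 2.5/97.5 percentiles. Prediction accuracy is the plain fraction
correct.

## Circuit maps

Neurons are assigned to layers by soma depth using half-open intervals
`[upper, lower)`; the packaged default boundaries (100, 310, 430, 600,
850 µm from the pia) are a documented convention standing in for an
atlas lookup and are fully configurable. Activation criteria follow the
mapping thresholds: a cell class counts as activated when its averaged
EPSP amplitude exceeds 3 mV and strongly activated above 7 mV. Input
matrices report group means with group sizes; combinations never
recorded stay absent (or `n = 0` under `complete = TRUE`) — an empty
cell is not a zero response. Normalization divides by a reference
population's mean. Dual-input convergence bins each neuron as
both/only-A/only-B/neither by a threshold on response magnitude; the
detection criterion is configurable because the source procedure never
states one.

## Patch-seq stage

The count simulator draws negative-binomial counts with per-gene
log-normal base means, per-cell library-size factors, and marker panels
that reflect excitatory cortical neurons (strong pan-neuronal and
excitatory markers; near-silent inhibitory and glial markers). The
planted QC structure is enforced exactly: designated low-depth cells are
scaled below the 500-count floor, designated contaminated cells have
their three inhibitory markers (Slc32a1, Gad1, Gad2) raised above the
log2-sum ceiling of 7, and every other cell is kept clean of both
failure modes. The packaged 91-cell fixture (4 low-depth, 7 contaminated,
seed 7) therefore passes exactly 80 cells — that worked example tests the
QC arithmetic, not the biology of a real cohort.

Gene gating keeps genes with count ≥ 5 in ≥ 10 cells; this is our
reading of the ambiguous printed phrase "expressed in fewer than ten
cells (count 5)", the only one consistent with both numbers. The bundled
differential-expression engine is a per-gene two-sided Wilcoxon rank-sum
test on `log2(x + 1)` values with Benjamini–Hochberg adjustment; fold
changes come from the back-transformed class means of the log values
with a pseudocount of 1. The engine is deliberately pluggable —
`call_degs()` consumes any per-gene `(log2FC, q)` table — because the
original analysis used an external shrinkage-based engine whose internals
are out of scope here; consequently the packaged engine will not
reproduce that engine's exact DEG counts on real data, only the
thresholding behavior (q < 0.05 and fold change > 2 or < 0.5).

## Axon profiles

Laminar profiles are one-dimensional intensity-versus-depth vectors; the
image-to-profile reduction happens upstream. The simulator builds a
per-layer block mixture (block height = target mass / layer width),
smooths it with a 20 µm Gaussian, and adds constant background and
noise; ground-truth fractions are recorded after smoothing, since
smoothing leaks a few percent of mass across boundaries. Operations are
background subtraction (clamped at zero), peak normalization
(idempotent; peak exactly 1), trapezoidal per-layer mass fractions
(summing to 100 within 10^−6^), and within-layer peak localization on a
0–100% depth scale with ties resolved to the shallowest sample. When
pooling slices, profiles are normalized per slice and then averaged.

## What the simulations do and do not show

Passing tests demonstrate that the estimators recover the quantities the
generators planted, under the stated protocols and noise levels:
calibrated sag cohorts (17 cells at 82.5 ± 8.6 pA/s, 13 at −3.1 ± 2.6,
as mean ± SEM) recover their generated group means within two SEM;
latency cohorts (20 neurons; 4.5 and 3.7 ms excitatory, 10.4 ms
inhibitory) recover programmed means within 0.3 ms; the 44-cell spiking
cohort with 29 burst-capable cells classifies as 66% burst-spiking; and
the classifier's cross-validated accuracy on cohorts drawn from the
printed group distributions exceeds its shuffled-label null. They do not
show that real recordings obey these models: real sag currents are
multi-exponential and voltage-dependent, real synaptic trains depress
and facilitate, real bursts ride slower conductances, and real Patch-seq
libraries fail in more ways than two. Problem sizes in the examples and
the reproduction script (tens of cells, thousands of genes, 1000
permutations) were chosen to mirror the source experiments' group sizes
while completing in minutes on a laptop.
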