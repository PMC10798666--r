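---
title: "Modeling variable-size Purkinje cell inputs to cerebellar nuclei neurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling variable-size Purkinje cell inputs to cerebellar nuclei neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbnsim)
```

## The scientific problem

Each glutamatergic projection neuron of the cerebellar nuclei (CbN)
receives convergent inhibition from dozens of Purkinje cells (PCs), which
fire spontaneously at 40–150 spikes/s. In juvenile mice the unitary
PC→CbN conductances are highly variable — right-skewed with a mean of
52.9 nS and a coefficient of variation of 1.0 before correction — rather
than uniform as older models assumed. `cbnsim` implements a complete
simulation pipeline to ask how that variability shapes what CbN neurons
transmit: how single inputs of different sizes imprint their timing on
CbN spiking (cross-correlograms), how they transfer a rate code, and how
synchrony and brief pauses among PCs drive CbN firing.

## Model components

### Spike trains

PC interspike intervals are modeled as i.i.d. lognormal draws. Recorded
PCs show a tight linear relation between the mean and standard deviation
of their ISI distributions, sd = −0.00154 + 0.583·mean (seconds), so a
single target rate fixes both moments; `isi_lognormal_model()` then
moment-matches the underlying normal parameters. The relation breaks down
(sd ≤ 0) at 378.6 spikes/s, which bounds the valid range. Two choices are
worth making explicit:

* **No explicit refractory period is imposed.** At physiological rates
  the lognormal places negligible mass near zero — P(ISI < 1 ms) < 1% at
  83 Hz — and that near-zero gap itself produces the refractory trough in
  the autocorrelogram and the pre-spike dip in the summed conductance.
  Imposing a hard dead time on top would double-count the effect.
* **Poisson controls** (`isi_poisson_model()`) use exponential ISIs with
  no refractory structure; they are the null against which the
  disinhibition effects are measured.

Trains are cumulative sums of ISI draws truncated at the requested
duration. Rate sweeps treat a rate of 0 as a silenced input (empty
train).

### The input population

`size_distribution_model()` packages the unitary conductance
distribution. The measurements give a histogram plus its first two
moments, not a parametric family, so the package uses a lognormal
calibrated to mean 52.9 nS and CV 1.0 — the simplest strictly positive,
right-skewed family matching both measured moments. A measured multiset of
conductances (CSV, one value per row) can be supplied instead and is
sampled with replacement, taking precedence over the parametric family.
Raw draws are corrected by ×0.4 for steady-state synaptic depression and
÷2.3 for the high-chloride recording internal, giving a corrected mean of
9.2 nS.

`draw_input_population()` accumulates corrected draws until the running
total reaches the target (200 nS by default, the estimated total PC
conductance onto one CbN neuron) and **keeps the overshooting draw**,
recording the actual total. Because the mean corrected draw is 9.2 nS
with CV 1, the kept overshoot makes the realized totals average roughly
209 nS rather than 200 nS. Treating "a 200 nS population" this loosely
is deliberate — the simplified 16×3 + 10×10 + 2×30 nS set sums to
208 nS and is handled the same way — but it does bias
total inhibition up by ~5% relative to an exact-200 normalization, which
matters when comparing absolute firing rates (see *Limitations*).

Synchrony is represented by group labels: inputs sharing a label share
one spike train, so synchronizing ten 5 nS inputs is, by construction,
exactly equivalent to one 50 nS input. The conductance synthesis
accumulates per-group impulse weights before filtering, which makes that
equivalence bit-exact rather than merely within floating tolerance.
Pauses delete every spike inside the pause windows and leave the
remaining spikes untouched; overlapping windows merge.

### Conductance synthesis

Unitary events are peak-normalized biexponentials
k(t) = A·N·(e^(−t/τd) − e^(−t/τr)). Inhibitory kernels use τr = 0.1 ms,
τd = 2.5 ms; excitatory (mossy-fiber) events use τr = 0.28 ms,
τd = 1.06 ms with amplitude 0.4 nS. The stated rise/decay times are
treated as the time constants of the biexponential (the convention of the
simulation environments this kind of waveform is usually built in), and
the declared amplitude is the kernel *peak*, matching how unitary input
sizes are reported from IPSC peaks. The per-unit-amplitude integral
(2.8589 nS·ms inhibitory, 1.7093 nS·ms excitatory) is exposed on the
kernel object so Campbell's-theorem oracles remain valid if the
convention is ever changed.

Traces are sampled by a pair of recursive one-pole filters, which is
exact at the sample points for this kernel and costs O(steps + spikes);
the default dt of 0.02 ms is a fifth of the fastest rise time.
Excitation is a single aggregate Poisson stream at the stated event rate
(20,000–25,000 events/s depending on protocol); per-fiber rates are not
resolved by the data and are not modeled. A 1 s burn-in is discarded
from all trace statistics to remove the filter-settling transient.

### The CbN neuron

The neuron is a single-compartment conductance-based integrate-and-fire
model, Cm dV/dt = gE(VE−V) + gI(VI−V) + gL(VL−V), with VE = 0 mV,
VI = −75 mV, threshold θ = −50 mV and reset Vr = −60 mV. Named presets
carry the per-protocol parameters (`"fig2"`: 50 pF, 8.8 nS, −40 mV,
2 ms refractory; `"fig4"`: 200 pF, 5 nS, −10 mV, 2 ms; `"fig8"` /
`"fig8-uniform"`: 70 pF, 20 nS, −49.9 mV, 1 ms) together with the
excitatory event rate used alongside them. The model is deliberately
passive-plus-threshold: no intrinsic pacemaker or rebound conductances.

Integration uses a per-step exponential update towards the instantaneous
steady state, which is exact for piecewise-constant conductances and
removes the stiffness error a forward-Euler scheme would accumulate at
the 0.1 ms synaptic rise. Threshold crossings are resolved at step
granularity (no sub-step interpolation); during the refractory period
the membrane is clamped at the reset and integration resumes afterwards.
The integration dt is a numerical choice, not a measured quantity; the
default of 0.02 ms was fixed by requiring that halving it changes
fluctuation-driven firing rates by well under 2%, which the test suite
verifies. Simulations start from the reset potential, and the first
second is excluded from rate estimates.

A closed-form oracle (`constant_conductance_rate()`) gives the exact
firing rate for constant conductances; the simulator is required to
match it within 1% at the default dt.

### Analyses

Cross-correlograms accumulate target spikes around every reference spike
within a ±10 ms window and carry two normalizations: spikes/s per
reference spike, and probability per reference spike per bin (their
ratio is exactly the bin width). Bins are centered so that lag 0 is a
bin center and the autocorrelogram's lag-0 probability is exactly 1.
Reference spikes closer than half a window to either end are dropped.
Several analysis constants are conventions rather than measured
quantities, and are therefore parameters with recorded defaults:

* bin width 0.1 ms (resolves the 1.5–3.5 ms refractory structure); 0.5 ms
  for pause PSTHs;
* baseline window −10…−5 ms, the flattest pre-event region;
* excitation *e* = fractional peak above baseline over lags [−5, 0) ms,
  inhibition *i* = fractional trough below baseline over [0, +5] ms;
* the half-decay time t½ runs from the trough to the first half-recovery
  of the deficit, measured after a 3-bin boxcar to stabilize the
  crossing.

Pause PSTHs are aligned to pause onsets, normalized by the mean rate in
the 5 ms before each onset, and the normalized peak is read either at
the maximum or at an imposed peak time (conventionally the one obtained
with 100% of inputs paused). Rate-code gains are least-squares slopes of
output versus input rate.

## Protocol drivers and problem sizes

The `run_fig*` functions reproduce the per-figure protocols end to end
and return plain data frames plus the configuration that produced them.
At full scale some of these protocols call for very long simulated times
(160,000 s per cell for the correlogram protocol); the package defaults
are scaled so each protocol runs in minutes on one CPU while keeping
correlogram standard errors well below the effect sizes — 2,000 s for
the correlogram protocol, 10 s per cell for the rate/CV population
(full scale), 100 s per rate-code condition (full scale), 200 s per
synchrony condition, and 1,600 s for the pause protocol. All
monotonic orderings are stable at these scales; quantitative targets
carry the stochastic draw-to-draw spread discussed below. Every driver
is bit-reproducible under a fixed master seed: the seed drives R's RNG
stream in a fixed draw order (populations, then trains in input order,
then the excitation stream inside the integrator), and per-condition
child seeds are derived arithmetically from the master.

Synchrony subsets are drawn uniformly over subsets of inputs (the
protocol description says only "a random subset"); subset identities are
reproducible from the seed. The uniform-size cells of the rate/CV
protocol use input sizes log-spaced over the stated 2.5–40 nS range with
counts keeping the total at 200 nS, and their trains use the lognormal
model at 100 Hz (in-vivo ISI sequences at that rate are not distributed
with the package; the lognormal at the same rate is its stand-in for
them). The three pause intervals (20/50/100 ms)
are configurable rather than fixed, since different parts of the
protocol description use different intervals.

## What the generator does and does not emulate

The synthetic inputs reproduce: the first two moments and right skew of
the unitary conductance distribution; the mean–sd relation and
refractory structure of PC ISIs; 100% spike-time synchrony; and pause
statistics. They do **not** reproduce: the exact tail shape of the
measured conductance histogram (only its moments); serial correlations
or slow rate modulations of real PC firing (ISIs are i.i.d.);
short-term plasticity beyond the static ×0.4 depression factor; or any
intrinsic CbN conductances. Passing tests therefore establish the
mechanism — disinhibition windows from refractory PCs, variance-driven
firing, amplitude-dominated synchrony and pause effects — under the
stated statistical model of the inputs, not a quantitative match to any
individual recorded cell.

## Numerical choices and degenerate inputs

Kernels are evaluated exactly at sample points by the recursive filter
(no truncation is needed); empty trains give zero traces; all-zero
traces flag their CV as undefined rather than dividing by zero; a
correlogram with zero baseline refuses to compute metrics; rate sweeps
reject degenerate (constant) input grids. Spike times are reported at
the end of the step in which threshold is crossed, so the minimum ISI is
t_ref + dt, satisfying the refractory invariant with step granularity.

## Limitations

Two known gaps matter when comparing absolute numbers. First, the
lognormal stand-in for the conductance histogram matches mean and CV but
not necessarily the tail mass, and fluctuation-driven firing rates are
sensitive to the largest inputs; population-average rates in the
rate-code protocol come out 15–25% below the reference example values
(126 and 35 spikes/s), which themselves sit in the upper range of the
draw-to-draw distribution. Second, the overshoot of the draw-until-total
rule adds ~5% mean inhibition relative to an exact-200 nS
interpretation; both effects push the same way. The orderings and
relative effects (which is what the protocols conclude from) are robust
to both.
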