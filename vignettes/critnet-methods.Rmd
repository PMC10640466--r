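---
title: "Methods: E-I balanced networks, criticality and the multilevel analysis stack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: E-I balanced networks, criticality and the multilevel analysis stack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

critnet simulates a small, dense network of conductance-based leaky
integrate-and-fire (LIF) neurons poised near an excitation–inhibition (E–I)
balanced critical state, and implements the analysis stack needed to
characterize its dynamics at several levels at once: neuronal avalanches and
their size statistics, the local-field-potential (LFP) proxy and its alpha
oscillation, stimulus-locked responses (ERP, ERD, PSTH), and spike-train
variability (CV, Fano factor). This vignette explains the model, the
estimators, the choices we made where the design was genuinely open, and
what the synthetic-data tests do and do not establish.

## The network model

Each of N = 500 neurons (80% excitatory) obeys

    tau dV/dt = (V_rest - V) + g_ex (E_ex - V) + g_inh (E_inh - V)

with tau = 20 ms, V_rest = -60 mV, firing threshold -50 mV, reset to
V_rest, absolute refractory period 5 ms, E_ex = 0 mV and E_inh = -80 mV.
Conductances are dimensionless (in units of the leak conductance). A
presynaptic excitatory (inhibitory) spike increments the conductance of its
postsynaptic targets by `dg_ex` (`dg_inh`), which then decays exponentially
with tau_ex = 5 ms (tau_inh = 10 ms). The reference inhibitory coupling is
`dg_inh = 5`; the excitatory coupling `dg_ex` is the control parameter,
critical near 0.4.

Every neuron receives an independent background Poisson train (20 spikes/s
by default) through an excitatory synapse, and optionally a stimulus: an
inhomogeneous Poisson train whose rate follows the alpha function
r(t) = a t exp(-t/tau_s) with a = r_max e / tau_s, so the rate peaks at
r_max (default 200 spikes/s) at t = tau_s (default 50 ms). The LFP proxy is
|I_ex| + |I_inh|, the absolute population means of the excitatory and
inhibitory synaptic currents. This proxy ignores the spatial organization a
real LFP reflects; it captures the collective oscillation only.

### Connectivity: why the inhibitory in-degree is regular

The connection density is p = 0.16. `build_network()` draws excitatory
synapses as independent Bernoulli edges, but gives every neuron exactly
`round(p * N_I)` = 16 inhibitory inputs (`method = "regular_inh"`, the
default). This is the one place where we found the network's qualitative
behaviour to depend on the sampling scheme, and the package's choice is
deliberate: with fully independent (Erdos-Renyi) edges the inhibitory
in-degree varies by +/-4 around 16, and the under-inhibited minority keeps
firing through the quiet phase of the collective cycle. Every realization
then drifts into a high-rate (~13 spikes/s), low-synchrony asynchronous
state with no alpha peak and no power-law avalanches. With a regular
inhibitory in-degree the post-burst silence is uniform and the
quiet-burst cycle is stable in every realization we simulated: ongoing rate
~3.4 spikes/s, population-rate fluctuation index ~2, LFP spectral peak at
10 Hz, pooled ISI CV ~1.2. Excitatory in-degree heterogeneity is harmless —
it adds realistic rate diversity across neurons — so it is kept. The fully
regular and fully Bernoulli samplers remain available as options, and
`is_degenerate_state()` screens simulations for the asynchronous mode
(fluctuation index below 1 with mean rate above 8 spikes/s; thresholds sit
between the two modes we measure, and are configurable).

### Integration

The integrator (C++) uses exponential-Euler for V with conductances held
constant across one step, and exact exponential decay for the conductances;
the step is dt = 0.1 ms. Spikes take effect on the next step (an optional
fixed transmission delay is available but defaults to zero, as the model
defines none). Refractoriness clamps V at the reset value with integration
suspended. Membrane potentials are initialized uniformly in
[V_rest, V_thresh) and a 2-s warm-up is discarded before any analysis.
Halving dt changes the 60-s ongoing rate by less than 5% (tested).
Background and stimulus spikes are realized per step as a Binomial(N, r dt)
count assigned to distinct uniformly chosen neurons, which is exactly N
independent Bernoulli thinnings; r dt must stay below 0.1. Trial ensembles
use consecutive seeds from a base seed and are bit-reproducible.

## Avalanches and criticality

Avalanches pool all spikes, bin them at the integration step, and take
maximal runs of consecutive occupied bins; the size is the run's spike
count (a distinct-neuron variant exists behind a flag). The size
distribution is tested against a doubly truncated discrete power law
P(s) ~ s^-alpha on [s_min, s_max]: alpha by 1-D maximum likelihood,
goodness-of-fit by the Kolmogorov-Smirnov distance on the truncated range,
calibrated with parametric surrogates that are refit before their distance
is measured (200 by default; the p-value is the fraction of surrogate
distances at least as large as the observed one). The truncation range is
searched over s_min in 1..20 and a logarithmic s_max grid, visiting wide
ranges first and accepting the first range with p > 0.2; candidates whose
observed distance already exceeds sqrt(n)-scaled bounds that no surrogate
set could rescue are skipped for speed. Under the null the p-values are
calibrated (rejection rate 0.05 +/- 0.02 at threshold 0.05 over 500
repetitions; tested).

The deviation-from-power-law statistic used for the coupling scan is
simpler, matching how the critical point is located: restrict the
empirical pmf to probabilities above 5e-5 (discarding the cutoff), fit a
straight line in log-log, and report the mean squared residual. Scanning
`dg_ex` over {0.2, 0.25, 0.3, 0.4, 0.5, 0.7, 1.0} at 20 Hz background
places the minimum at 0.4, with the network silent below 0.25 and an
excess of large avalanches at 1.0. The deviations at 0.4 and 0.5 are
close (the critical region is a plateau, not a needle), so the scans run
240 s per grid point, at which the ordering is stable across seeds.

E–I balance is quantified by mean(I_ex + I_inh)/mean(I_ex) in 2000-ms
windows. In our simulations this ratio is small and negative (-0.1..0)
across dg_ex 0.4–0.5 and clearly positive by 0.7; the literal zero
crossing lands between 0.5 and 0.7 depending on background rate, slightly
above the deviation minimum at 0.4. We report the measured crossing rather
than forcing agreement.

## Spectra, wavelets and response curves

The LFP spectrum is an averaged periodogram: mean-removed, Hann-tapered
2-s segments with 50% overlap (both configurable). Spectral peaks are read
after a 3-point moving average. Time-frequency maps use complex Morlet
wavelets with 6 cycles at every frequency (grid 2–50 Hz); the map is the
trial-averaged modulus, and samples within one wavelet support (3 SD) of
either end are flagged per frequency. The alpha-power course is the 8–12 Hz
band mean; ERD baselining (subtract the mean over [-800, -200] ms) is
available but off by default since the raw course is what the trial
figures show. The ERP is the pointwise trial mean of the aligned LFP. The
PSTH emulates a multiunit recording: 20 neurons chosen once per ensemble
with the ensemble seed, counted in sliding 5-ms windows, averaged over
trials, in spikes/s per neuron.

## Variability

CV is the sample standard deviation (n-1) of ISIs over their mean; FF is
the across-trial variance over mean of multiunit spike counts in 100-ms
windows. The windowed CV course merges the multiunit train within each
window and either pools ISIs across trials (default) or computes a CV per
trial and averages (`per_trial = TRUE`) — the latter matches how a
trial-averaged variability figure is assembled, and the two disagree
when the ongoing state is strongly burst-structured: pooling mixes
window-phase variability into the baseline CV (~2.6 at the critical
point), while per-trial averaging gives ~1.3. Windows with too few
intervals are NA, never zero.

## Scaled problem sizes

The package's own tests and the reproduction script run at desk scale,
chosen once: 120 s of ongoing activity per scan point (the deviation
curve is stable from ~60 s), at least 20,000 avalanches for the power-law
fit, and 200-trial ensembles for response statistics (the reference
figures use 1000; 200 leaves the PSTH, ERD and ERP features clearly
resolved while keeping a full run in minutes).

## What the model does and does not reproduce

Reproduced robustly across seeds: the silent/active transition at
dg_ex ~ 0.25 and at ~8-10 Hz background; the 10 Hz LFP peak at 20 Hz
background; the deviation minimum at dg_ex = 0.4 with an acceptable
truncated power law (surrogate p ~ 0.3); pooled ongoing CV ~1.2 with the
ISI mode near 100 ms; stimulus-induced alpha suppression with later
recovery; an ERP with a sharp early peak and a broader late deflection;
Fano-factor reduction during the response; and the qualitative failure of
both patterns away from criticality (sparse burst response without
ongoing alpha at dg_ex = 0.25; frequency shift instead of suppression at
dg_ex = 1.0).

Known quantitative departures, reported as measured: our PSTH
peak-to-baseline ratio is ~5 (reference: ~3) because the first
stimulus-locked population burst is sharper and more phase-locked than in
the reference data; the oscillation peak drifts from ~7.5 Hz at 15 Hz
background to ~13-15 Hz at 30-40 Hz rather than staying inside 8-12 Hz;
and the current-ratio zero crossing sits one grid point above the
deviation minimum. The windowed CV during the response is flat-to-down
rather than clearly up; the per-trial course shows the rise only at the
response onset and offset. These are properties of the minimal model as
specified — we chose not to add mechanisms (synaptic delays, weight or
parameter heterogeneity) that the model definition does not contain, after
verifying that plausible variants (transmission delays of 0.5-2 ms,
excitatory-only stimulus targeting) move some of these numbers toward the
reference at the cost of others.

## What the synthetic fixtures establish

The generators (`sample_discrete_powerlaw`, `gen_poisson_ensemble`,
`gen_gated_tone`) provide ground truth for every analysis operator:
exponent recovery within +/-0.05 at n = 1e5, K-S calibration under the
null, CV = 1/FF = 1 on Poisson and 0 on periodic trains, spectral and
wavelet peak localization within one grid step, and hand-traced avalanche
segmentation. Passing these shows the estimators are correct, not that
the network model is a faithful account of cortical tissue; the fixtures
deliberately lack the nonstationarity, measurement noise and spatial
structure of real recordings.
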