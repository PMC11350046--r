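---
title: "Models and measurement conventions in tauhcn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and measurement conventions in tauhcn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tauhcn)
```

tauhcn re-implements, as a tested pipeline, the quantitative analyses used
to characterize a tauopathy phenotype coupled to HCN channelopathy:
intrinsic membrane properties and hyperpolarization-induced voltage sag,
spontaneous excitatory postsynaptic current (sEPSC) detection and kinetics,
presynaptic vesicle ultrastructure, and dendritic morphometry. Because no
experimental recordings ship with the package, a synthetic-data module
generates every input type with controllable ground truth, and the test
suite exercises the full measurement chain against it. This vignette
documents the models, the measurement conventions, the calibration of the
genotype presets, and the limits of what the synthetic validation shows.

## The neuron simulator

`simulate_neuron()` integrates a single-compartment membrane with a leak
conductance, an h-current (the HCN-channel current, gate $m$ opening on
hyperpolarization with $m_\infty(V) = 1/(1+\exp((V-V_{1/2})/k))$) and a
non-inactivating potassium conductance (gate $n$, opening on
depolarization):

$$C_m \dot V = -g_L (V - E_L) - g_h m (V - E_h) - g_K n (V - E_K) + I(t).$$

Defaults: $C_m = 100$ pF, $g_L = 10$ nS, $E_L = -80$ mV, $E_h = -30$ mV,
$V_{1/2,h} = -82$ mV, $k_h = 7$ mV, $\tau_h = 100$ ms, $g_K = 2$ nS,
$E_K = -100$ mV. The stated gating equation fixes only the h-gate
orientation; the potassium gate uses the physically sensible
depolarization-activated sign, and carries its own time constant
($\tau_K = 50$ ms). Integration is fixed-step 4th-order Runge-Kutta at
$dt = 0.05$ ms -- deterministic and accurate to well below measurement
resolution for these millisecond-scale gating kinetics -- with the
injected current held piecewise constant over each integration interval so
that a step onset is exact rather than smeared across a step. A holding
current keeps the pre-stimulus potential at $-80$ mV, as in the recording
protocol the simulator emulates (500 ms, $-100$ pA hyperpolarizing step).

The genotype presets differ only in $g_h$: WT uses 2 nS; the Tau35 preset
uses 6.24 nS, fixed by a one-time brute-force sweep so that the measured
subtraction sag roughly doubles -- the modelled consequence of elevated
HCN1/HCN3 expression. The sweep also shows `sag_sub` increasing
monotonically in $g_h$ over 0-10 nS, which the tests assert.

## Sag and passive properties

`fit_passive_response()` quantifies a hyperpolarizing step response using
the field's two sag conventions. With baseline $V_0$ (mean over the 50 ms
before onset), deflection minimum $C$, steady-state deflection $A$ (mean
over the last 20% of the step) and a single-exponential fit
$B(1-e^{-t/\tau_m})$ restricted to the initial falling phase where the
deflection lies between $0.10\,C$ and $0.90\,C$:

* `sag_sub` $= 100\,(C-A)/C$ — from raw extrema,
* `sag_fit` $= 100\,(B-A)/B$ — from the fitted asymptote,
* $R_{in} = A/I_{step}$, and the rebound is the maximum voltage above
  baseline within 200 ms after step offset.

The windows (50 ms baseline, last-20% steady state, 200 ms rebound) are
this package's choices; the quantities they estimate are insensitive to
them for time constants an order of magnitude shorter than the step. The
fit-domain reading "deflection between 10% and 90% of the minimum" is the
only one that yields a monotone fit segment. Non-convergent fits are
flagged rather than fatal: `sag_fit` is `NA` and `fit_converged` records
the failure.

## Conductance activation

`analyze_iv()` reduces a 12-step voltage-clamp family ($-90$ to $+20$ mV,
10 mV increments, 30 ms steps) to a per-cell Boltzmann activation curve.
An ohmic leak is fitted to the two most hyperpolarized steps -- assuming
the channels are closed there -- and subtracted everywhere; steady-state
currents are normalized to membrane capacitance; and the specific
conductance uses a fixed 100 mV potassium driving force by default. That
fixed denominator reproduces the assay convention literally; the
physically motivated $V - E_K$ denominator is available via
`driving = "physical"` but off by default (fidelity first). One knock-on
effect is documented in the tests: because the Boltzmann conductance is
not exactly zero at $-90$/$-80$ mV, the leak estimate absorbs a $\sim
3\times10^{-4}$ fraction of $G_{max}$, so even noiseless model currents
are recovered near-exactly rather than bitwise.

## sEPSC detection and waveform statistics

`detect_events()` implements a Clements-Bekkers-style template search: a
biexponential template (unit negative peak) is optimally scaled and offset
at every position, and the detection criterion is the fitted scale divided
by the standard error of the fit. The same WT-kinetics template is used
for both genotypes, as a single Clampfit template would be -- this avoids
circular per-group tuning. Three deterministic post-rules replace the
manual accept/reject pass of interactive analysis:

1. one event per contiguous above-threshold region of the criterion (at
   its maximum), since slow events under a fast template hold the
   criterion above threshold for $\sim$10 ms;
2. a 5 ms refractory between events;
3. amplitude screening: fitted amplitude at least 3 robust (MAD-based)
   noise SDs, and candidates within one template length after a kept
   event are dropped if their amplitude is below 70% of it (decay
   "shoulders").

The default criterion threshold of 4 was calibrated on noise-only traces
(at most one false positive per 30 s trace on average). At the presets'
SNR of 10, sensitivity against ground-truth event times exceeds 0.95 and
false positives are rare; the residual loss is dominated by event pairs
closer than the refractory period, which costs the higher-rate genotype
$\sim$3% of events.

`average_events()` aligns snippets on the detection time and uses a
second pass that realigns each snippet on the first-pass mean by
cross-correlation; without it, the template-mismatch jitter of the slower
genotype smears its average and biases the rate of rise upward. Waveform
statistics follow the averaged-event convention: amplitude is the absolute
extremum relative to a baseline taken more than 10 ms before the
alignment point; half-width is the time beyond half amplitude with linear
interpolation at the crossings; the rate of rise is the steepest 0.4 ms
centered secant on the rising phase (a single-sample difference is
dominated by noise on averages of few events). Frequency is simply the
event count over the 30 s recording.

The Tau35 kernel time constants ($\tau_{rise} = 2.716$ ms,
$\tau_{decay} = 7.250$ ms, vs WT $0.8/4$ ms; equal amplitudes) were fixed
once by root-finding on the sampled analytic kernel pushed through exactly
this measurement chain, so that the true rate-of-rise ratio is 0.43 and
the true half-width ratio 2.3. Event rates encode the configured 77%
frequency reduction (2.0 vs 0.46 Hz).

## Vesicle maps and nearest-neighbor clustering

`generate_vesicle_map()` draws the vesicle count from a negative binomial
(dispersion 10 -- overdispersed, as biological counts are, but still
mean-controlled), places a small docked subpopulation along the active
zone with membrane gaps under 2 nm, scatters the rest as an isotropic
Gaussian cluster, and enforces a hard core of one mean vesicle diameter
(40 nm) between all centers by rejection sampling (an error suggesting a
larger `cluster_sd` is raised if packing is infeasible). Dense-core
vesicles are a separate class: present with probability `dcv_prob`,
excluded from SV counts and from nearest-neighbor analysis.

The analysis side mirrors the published procedure: only synapses with a
defined PSD and 10-250 SVs enter (`filter_synapses()`; published EM protocols of this kind state either 250 or 200 as the upper bound; 250 is the default here and the bound is a parameter); `nn_analysis()` computes per-vesicle nearest-neighbor center
distances; `group_nn_summary()` averages cumulative frequency curves and
mean NN distances per synapse, unweighted -- every synapse counts equally
regardless of its vesicle count. A test asserts that this convention
differs measurably from pooling vesicles on unbalanced groups, so the two
cannot be silently interchanged. The docked criterion (membrane within
2 nm of the active-zone segment) is this package's explicit definition;
docked percentages are routinely reported in this assay without a stated criterion.

Cluster spreads were calibrated by brute-force simulation (well over
$10^4$ vesicles per setting): WT 200 nm at both ages; Tau35 236 nm (4
months) and 210 nm (10 months), so the true group mean NN gap is 10 nm at
each age given each age's count presets. Count means encode the 27%/39%
SV reductions and the 74% DCV-prevalence reduction at 10 months.

## Morphologies

`generate_morphology()` grows each of 10 primary dendrites from a point
soma and lets every segment end bifurcate with probability `branch_prob`
up to depth 2, then places spines along the cable as a Poisson process
with type-conditional geometry. The flat topology is deliberate: with the
same expected branch-point count spread over fewer, deeper primaries, the
branch count per neuron is approximately a critical branching process
whose variance (sd $\sim$8 at mean 9) would swamp a 50-neuron comparison;
with many shallow primaries the count is binomial (sd $\sim$1) and the
group contrast is estimable at the study size. WT uses branch probability
0.9 and 30 um segments (expected 9 branch points, 84 um mean dendrite
length); Tau35 uses 0.504 and 33.47 um, encoding the 44% branch-point and
20% length reductions. Spine densities are 0.80 vs 0.328 per um (59%
reduction), with Tau35 shifting type mass from mushroom to thin spines.

`sholl()` counts sphere crossings per segment by solving the
sphere-segment quadratic, counting parameter roots in $[0, 1)$ -- so a
node exactly on a sphere is counted once, with the crossing assigned to
the outgoing segment, and a straight 100 um neurite crosses radii 10-90
but not 100. `branch_metrics()` counts dendritic nodes with two or more
children and divides total cable by the number of primary dendrites;
`classify_spine()` is a deterministic head/neck-ratio rule (mushroom:
head/neck > 1.5 and head > 0.35 um; stubby: length/neck < 1; thin
otherwise), stated explicitly because the type names are conventionally used without published criteria. Under the generator's type-conditional geometry the rule
recovers the generating label on more than 95% of spines.

## Statistics and reporting

`group_t_test()` is the classic pooled-variance two-tailed Student test
(Welch's correction is deliberately not applied: the classic Student form is the convention this pipeline reproduces), with a $p = 1$ convention for identical constant groups.
`anova2_tukey()` fits the two-way crossed model with Type II sums of
squares -- robust to the unbalanced group sizes synthetic filtering can
produce -- and Tukey HSD on
the cell means. Stars follow the 0.05/0.01/0.001/0.0001 convention. No multiple-testing correction is applied across metrics -- a deliberate choice the report metadata records. `run_pipeline()` drives
generation-plus-analysis end to end and writes feature tables, group
summaries, test results and a JSON of headline percent changes; the same
seed reproduces identical outputs byte for byte.

## Sample sizes, seeds and runtime choices

The recovery checks use the study's own group sizes: 20 thirty-second
recordings per genotype for sEPSC statistics, 16 synapses per group for
the clustering comparison, 100 (counts) and 200 (DCV prevalence) synapses
for the ultrastructure rates, and 50 morphologies per genotype. Cohorts
compared across genotypes are generated with paired seeds (common random
numbers): this leaves every group-level estimate unbiased while removing
the shared count-draw noise from group differences -- without it, the
16-synapse NN-gap estimator has a standard error as large as the 2 nm
band used to judge it. Monte-Carlo property tests (detector false-positive
rate, type-I error, null ANOVA uniformity) use fixed seeds and a few
hundred to a few thousand replicates, enough to pin the quantities at the
asserted tolerances while keeping the default suite in the minutes range.

## What passing tests do and do not show

The synthetic module reproduces the statistical structure the analyses
assume -- Poisson event trains with biexponential kernels in Gaussian
noise, clustered hard-core point patterns, branching trees with typed
spines -- and the pipeline demonstrably recovers the configured effect
sizes from raw synthetic inputs. Real recordings differ in ways the
generator does not model: cell-to-cell parameter variability (no distributional information is available for it, so presets are spherical single-value choices), correlated and non-Gaussian noise, series
resistance and space-clamp artifacts, amplitude heterogeneity across
synapses, section-plane effects in 2-D vesicle projections (no 3-D
correction is attempted), and reconstruction errors in traced
morphologies. Passing tests therefore validate the measurement chain and
its conventions, not the biology; effect sizes recovered from real data
would additionally reflect all of the above.
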