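---
title: "Methods: models, parameters and design choices in optomap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in optomap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optomap)
```

## The measurement problem

In two-photon optogenetic connectivity mapping, candidate presynaptic
neurons expressing an opsin (e.g. ChrimsonR restricted to a Cre-defined
subclass) are photostimulated one at a time while one to four patched cells
are held in current clamp. Each probed pair yields a set of stimulus-aligned
voltage sweeps; the analysis must decide whether a stimulus-locked
postsynaptic potential (PSP) is present, quantify it, and turn thousands of
such calls into connection-probability maps, comparisons across cell
classes, and higher-order motif statistics. Because a photostimulus has
finite spatial resolution, the analysis must also quantify how often a
*neighbor* of the targeted cell fires instead ("off-target activation"), and
how that inflates apparent connectivity.

`optomap` implements that full computational chain, together with seeded
generators for every input, so that each estimator can be validated against
ground truth without any recorded data.

## PSP detection and quantification

**Quality control.** A sweep is excluded when the median voltage in the
50 ms before the stimulus deviates from the holding target by more than
5 mV, or when the voltage drifts by more than 1 mV within that window. Drift
is measured as the difference between the medians of the window's last and
first 10 ms: a plain range would reject clean sweeps at realistic noise
levels, while the median difference catches ramps and large spontaneous
events.

**Baselining.** The median of the 20 ms immediately before stimulus onset is
subtracted per sweep, so the pre-stimulus median of a baselined sweep is
exactly zero.

**Exponential deconvolution.** Detection operates on
`D(t) = V(t) + tau * dV/dt` with `tau = 20` ms. For a PSP decaying with time
constant `tau` this collapses the response to an impulse at its onset, which
separates temporally summed PSPs. The derivative uses central differences
(second-order accurate, symmetric; one-sided at the trace edges).

**Detection windows.** Peaks of the deconvolved average response are sought
0–50 ms after stimulus onset, with the threshold at 5 times the SD of the
deconvolved trace in a 20 ms pre-stimulus window. A single peak defines a
measurement window from the first threshold crossing to 20 ms later;
multiple peaks split the windows at the inter-peak minima. Three numerical
choices matter at high sampling rates (traces are analysed at their native
25–100 kHz): the deconvolved trace is smoothed with a 0.5 ms boxcar *for
detection only* (the derivative term otherwise amplifies sample-scale
noise), local maxima closer than 2 ms are merged, and two maxima only count
as separate events when the valley between them returns at least half-way to
threshold. Ties at the peak value resolve to the first sample.

**Metrics.** Amplitude is the peak of the averaged response in the detection
window; the CV is the SD/mean of per-sweep peaks measured in the same window
(we assume the same window for both, the natural reading of the procedure).
The 20–80% rise time interpolates linearly between samples and is undefined
for responses of 0.1 mV or less. Inhibitory responses recorded at –55 mV
holding are sign-flipped before detection, so one polarity-agnostic pipeline
serves both polarities.

**Paired-pulse ratio.** For photoresponses with two distinct PSPs, each
sweep is deconvolved and the peaks inside two operator-set windows are
measured; the PPR is the second peak over the first, and the inter-PSP
interval is the peak-time difference. Population summaries keep only sweeps
with intervals of 5–10 ms. When `tau` is not given it is chosen from
{5, 10, 15, 20} ms to minimize the mean |D| in a 10 ms window starting 3 ms
after the second deconvolved peak: both overshoot and undershoot of the
baseline raise that score, so the grid picks the value closest to the true
decay (an automated version of adjusting `tau` by eye; the absolute value
prevents overshoot–undershoot cancellation from gaming the choice).

**Rundown.** The OLS slope of amplitude against stimulus number, reported as
percent of the fitted initial amplitude per stimulus so that a linear
1%-per-sweep decay reads exactly –1.0.

## Connection classification

Two independent pathways mirror the study design. The **SVM pathway** trains
a radial-basis support-vector machine (features z-scored on the training
split, 40–60% train–test split, seeded) on eleven features of each
photoresponse: four from the average response (peak, time of peak,
across-sweep SD at the peak time, baseline SD), five from the deconvolved
average (peak, its time, baseline SD, counts of 3x- and 5x-SD upward
crossings) and two from individual deconvolved sweeps (mean and SD of
per-sweep 3x-SD crossing counts). Excitatory and inhibitory datasets are
trained separately. The **z-score pathway** is annotation-free: the peak of
the average response in the 50 ms post-stimulus window, divided by the
baseline SD, is compared against the 99th percentile of the same statistic
computed in a 50 ms control window 70–20 ms before onset, pooled over the
dataset. The threshold is computed per polarity (the alternative, pooling
polarities, would mix datasets recorded at different holding potentials and
noise levels). By construction about 1% of unconnected pairs are flagged;
calls use a strict inequality, so a value exactly at threshold is not
connected.

**Direct artifacts.** In opsin-positive patched cells, photostimulation near
the soma depolarizes the cell directly; such responses begin at stimulus
onset, while synaptic responses lag by a synaptic delay. Responses whose
detected onset falls within 1 ms of stimulus onset (the margin makes the
qualitative "coincident onset" rule operational) are excluded, and excluded
pairs never enter connection-probability denominators.

## Photostimulus resolution and off-target activation

Loose-seal spike-outcome tables (10 trials per condition; an ascending power
series on target, a 7-spoke radial grid at 10/20/30 um lateral offset, and
10 um axial steps) yield: the minimum reliable power (smallest tested power
with spiking on every trial), first-spike latency and its SD (jitter,
sample SD), and spike probability versus offset. The latter is fit per axis
with `p(d) = A exp(-d^2 / (2 sigma^2))`, `A` constrained to (0, 1], centered
at zero, no baseline term (probability vanishes at large offsets);
`FWHM = 2 sqrt(2 ln 2) sigma` exactly. Spokes at the same distance are
averaged (for a least-squares fit this is equivalent to fitting the
per-spoke points, since they share the regressor). Probabilities that do not
decrease with offset return an infinite-width sentinel with a warning.

Off-target estimation combines three ingredients on a common
10 um x 10 um (lateral x axial) grid:

1. an **edge-corrected neighbor histogram** — for each labeled cell, lateral
   (radial in the imaging plane) and axial offsets to every other cell are
   binned, and each bin is normalized by the number of seed cells whose full
   annulus-and-slab region fits inside the imaged volume, which keeps bins
   unbiased near the boundaries (the targeted cell is excluded from its own
   neighbor counts);
2. an **activation-probability map** under the *min rule*: the probability
   at a combined offset is the lower of the two axis-Gaussian predictions (a
   conservative choice, since the true falloff with combined offsets is at
   least as steep as either axis alone), evaluated on a 1 um grid and
   averaged per bin; the probability at zero offset is 1;
3. their product, summed over bins, giving expected off-target activations
   per stimulus.

A homogeneous-density variant integrates the min-rule probability over
space (`density x int int min(g_lat(r), g_ax(z)) 2 pi r dr dz`, adaptive
quadrature at relative tolerance 1e-6) and is linear in density. A direct
Monte-Carlo oracle (Poisson placement plus Bernoulli activation, 1e4–1e5
points) validates both estimators in the tests. Finally,
`p_response(p, n) = 1 - (1 - p)^n` gives the probability of observing a
response when a stimulus activates `n` cells sharing connection
probability `p`.

## Connectivity statistics

Connection probabilities are binned (half-open 100 um bins by default) along
presynaptic pia distance, horizontal offset or 3D distance, with 95%
Jeffreys intervals — equal-tailed quantiles of
`Beta(found + 1/2, probed - found + 1/2)`, lower limit 0 at zero found and
upper limit 1 at found = probed. Jeffreys coverage oscillates around the
nominal level and dips slightly below at some (p, n); the tests therefore
check empirical coverage against the exact finite-sample coverage rather
than a blanket bound. Figure-style `drawn` flags (fewer than 20, or 10,
probed) are parameters and never silently applied to statistics.

Contingency tests are two-sided Fisher exact tests in the classical
minimum-likelihood definition (all tables with point probability at most
that of the observed table), with rows = groups and columns =
(found, not-found); a zero margin returns p = 1. Multiple comparisons use
Benjamini–Hochberg step-up adjusted p-values (rejections reported at the
requested FDR). Binned trends use Pearson chi-squared on the k x 2 table
with k − 1 df. The cross-method comparison (optogenetic mapping versus
paired recordings) reports per-category Fisher + BH, the Pearson correlation
between the two probability vectors, and unweighted OLS of the optogenetic
on the paired probabilities with coefficient standard errors. Effect sizes
use Cohen's d with the pooled-SD denominator
`sqrt((SD1^2 + SD2^2)/2)`; omnibus group differences use Kruskal–Wallis
followed by Dunn's rank-based pairwise z tests (tie-corrected,
Holm-adjusted by default).

One reference value deserves a note: among the published group comparisons
shipped with the package, the L5 Pvalb versus L5 Sst counts (2/259 vs
16/252) give p = 5.2e-4 under the correct (found, not-found) table
construction; the value printed alongside those counts (1.1e-3) is
recovered only if the columns are laid out as (found, probed-total). The
package reports the correct construction and exposes the discrepancy in its
tests.

## Motif analysis

Convergence motifs are unordered pairs of photostimulated cells connected to
the same patched cell; divergence motifs are unordered pairs of patched
cells receiving input from the same photostimulated cell. Completed-motif
curves enumerate *ordered* pairs (both orders counted): given that cell *i*
is connected, the fraction of pairs in which cell *j* is too, binned by
distance (between presynaptic cells or from cell *j* to the target for
convergence; 3D intersomatic distance between the patched cells for
divergence, optionally restricting cell *j* to a postsynaptic subclass).

The bootstrap null preserves every probed pair's geometry and subclass and
redraws only the Bernoulli connection outcome at the pair's binned
probability (horizontal offset x presynaptic pia distance, 100 um x 100 um,
by Cre line and postsynaptic subclass). Bins with zero found connections
contribute probability 0; an optional add-one smoothing flag defaults off.
One-sided p-values are the fraction of simulations with a motif count at or
above the observed one, reported as `< 1/n_sim` when none reaches it. Two
properties matter for interpretation. First, estimating the probability
table from the same dataset (the plug-in null, as used in practice) makes
the p-values conservative — the simulations partially track the observed
fluctuations. `bootstrap_motif_test()` therefore also accepts externally
supplied per-pair probabilities, and the calibration tests verify exact
uniformity (via the randomized probability integral transform over the
returned simulated counts) when the true generative probabilities are
supplied. Second, power: planted divergence hubs (one presynaptic cell
wired to five recorded cells in a 5% network) are detected at p < 0.05 in
essentially every replicate even with the plug-in null.

Amplitude correlations across connections sharing a cell use the
double-plotting convention: each unordered pair enters twice, once in each
axis assignment, and Pearson's r is computed on the doubled set while the
p-value uses the number of *unique* pairs as the sample size.

## The synthetic experiment generator

All generator randomness flows from one integer seed through named
substreams, so adding sweeps to one pair never perturbs another and every
dataset is bit-reproducible.

* **Cell maps** are homogeneous Poisson point processes in a bounded volume
  (per-layer slabs when a density is given per layer). The default mapping
  volume is 300 x 600 x 120 um with 8000 labeled cells/mm^3, inside the
  measured range of labeled-cell densities (~2000–22,000 cells/mm^3).
* **Networks** draw independent Bernoulli edges from a distance kernel;
  the default `0.25 exp(-d / 150 um)` reproduces intralaminar probabilities
  of ~5–25% over the probed distances.
* **Synapses** follow a binomial quantal model: `n_sites` sites releasing
  with probability `p`, quantal size `q`, mean amplitude `N p q` and
  CV `sqrt((1-p)/(N p))`, which yields the skewed amplitude distributions
  and the inverse CV–amplitude relation seen across connections. Default
  draws (`N ~ 1 + Pois(4)`, `p ~ U(0.3, 0.9)`,
  `q ~ logNormal(log 0.15, 0.4)`) put the amplitude median near 0.3 mV.
  The PSP kernel is an amplitude-normalized difference of exponentials,
  1.5/18 ms (rise/decay) for pyramidal targets and 0.8/8 ms for fast-spiking
  targets, chosen to reproduce the observed 20–80% rise-time ranges.
* **Photo-evoked spiking**: log-normal-like minimum reliable powers, 1–3
  spikes per stimulus (probabilities 0.7/0.25/0.05), first-spike latency
  6 ms with 0.7 ms jitter (short-latency, sub-millisecond-to-2-ms regime of
  on-target stimulation), Gaussian falloff with lateral sigma 8 um and
  axial sigma 20 um (FWHM 18.8 and 47 um, inside the measured 12–23 and
  38–75 um ranges). Below the minimum reliable power, spike probability
  scales as the cubed power ratio; at or above it, on-target probability
  is exactly 1, which realizes the 10/10 definition.
* **Noise**: an Ornstein–Uhlenbeck process (exact AR(1) discretization)
  with 5 ms correlation time and 0.1 mV SD — membrane noise is temporally
  correlated, and an uncorrelated process would make the deconvolution
  threshold unrealistically forgiving. Spontaneous PSPs arrive as a Poisson
  process; the rate is not quantified in the source data, so the default
  (0.5 Hz, exponential amplitudes with 0.2 mV mean) is a deliberately
  modest level that exercises the QC and false-positive paths without
  dominating them, and is a free parameter. Direct artifacts on
  opsin-positive patched cells rise exactly at stimulus onset with 0.23 mV
  amplitude (the reported median).
* **Intrinsic sweeps** synthesize 1 s current steps (–130 pA upward in
  20 pA steps, extended past +250 pA when the rheobase demands) from target
  features: RC charging with a slow sag component whose weight is solved
  numerically so the realized (peak − steady)/peak equals the requested sag
  ratio; stereotyped triangular action potentials whose peak, trough,
  half-height width and upstroke/downstroke ratio are exact by construction
  (segment durations snapped to the sample grid); spike trains with
  constant-ratio inter-spike intervals so the adaptation index is exact;
  and rates following the requested f-I slope. Feature extraction then
  inverts the generator within stated tolerances: input resistance from
  steady-state deflections, the membrane time constant from a
  free-asymptote exponential fit to the charging phase (excluding the
  smallest hyperpolarizing step, and robust to the sag component), AP shape
  from the first spike at rheobase, rate/adaptation at rheobase + 40 pA.

What the generator does **not** emulate: polysynaptic and network-state
events, electrode drift and access-resistance changes, dendritic filtering
differences within a class, opsin photocurrent kinetics, conductance-based
spike generation, or severed-axon geometry near slice surfaces. Passing
tests therefore demonstrate that the estimators are correct under the
stated statistical structure, not that real recordings satisfy that
structure.

## Interneuron clustering

Fourteen intrinsic features (resting potential, input resistance, time
constant, capacitance, sag, rheobase, AP width/upstroke-downstroke
ratio/peak/trough/height, firing rate, adaptation, f-I slope) are z-scored
and clustered into three components. The mixture uses diagonal covariance
("VVI"): full covariance would need 105 free covariance parameters per
component in 14 dimensions, far more than typical interneuron counts
support, and the simulated populations have independent features. EM is run
from a 50-restart k-means solution plus ten random initializations, keeping
the highest log-likelihood — single-start EM lands in merged-cluster local
optima on a noticeable fraction of draws. Components map to class labels by
total standardized distance between cluster centroids and the reference
class means (best assignment over all permutations): single-feature
signatures, e.g. sag for putative Sst cells, overlap too much between the
VIP-like and Sst-like populations to be reliable on their own. A Ward
agglomerative alternative is available behind a flag; it recovers most of
the structure but is the weaker pathway.

## Degenerate inputs and conventions

* Layers are half-open `[lo, hi)` bins of pia distance (a cell exactly at
  330 um is L4); distances beyond 1000 um return a "below L6" sentinel.
* The stage frame is right-handed with the optical axis along z; slice
  rotation acts about that axis; positive horizontal offsets are posterior.
* Connection tables serialize floats with 6 significant digits; text and
  integer columns round-trip exactly; unknown columns are preserved.
* Fixed representative layer boundaries are used throughout (no per-slice
  adjustment; the alternative is not identifiable from the data shipped
  here).
* Pooled (not per-cell) resolution fits feed the off-target maps by
  default.
* The motif null redraws only the probed pairs' Bernoulli outcomes; cell
  geometry is never re-placed.
* All measurement windows are rounded to the nearest sample at the native
  sampling rate.

## Problem sizes used by the tests

The test-suite and acceptance fixtures are sized to the regime where each
property is identified: 20-sweep responses at 25 kHz for amplitude recovery
(40 fixtures), 1000 sweeps for the quantal-CV closed form, 300 noise-only
responses for the z-score false-positive rate, 200 replicate datasets of
150 probed pairs (199 bootstrap simulations each) for null calibration, 40
replicates for planted-hub power, 60-trial loose-seal protocols for
resolution recovery, and 30 cells per class for cluster recovery. These are
the package's own validation choices; every one of them can be scaled up by
re-running the same functions with larger arguments.

## Known limitations

The plug-in motif null is conservative (see above); completed-motif ordered
pairs share underlying connections, so their pointwise binomial intervals
understate the dependence (the tests validate them as unbiased against the
realized marginal); the SVM pathway requires labeled training data and is
only as good as those labels; and the HDF5/NWB sweep container of the
original acquisition chain is out of scope — sweep sets are serialized as
plain long-format CSV, and recorded datasets enter through the
connection-table CSV interface.
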