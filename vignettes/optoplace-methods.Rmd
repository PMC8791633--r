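---
title: "Methods: opto-tagging classification and spatial-coding analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: opto-tagging classification and spatial-coding analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optoplace)
```

`optoplace` analyzes single-cell recordings from freely moving animals in
which a recorded neuron's molecular identity is probed optogenetically: if
the neuron expresses a light-gated channel, brief blue-light pulses evoke
spikes at short, reliable latency; if it is driven only synaptically, evoked
spikes come later and fail more often. The package couples that
classification with a quantification of spatial coding on a closed maze.
This vignette explains the models and conventions behind each stage, the
parameters that matter, and what the synthetic benchmark does and does not
establish.

## Opto-tag classification

**Pulse inclusion.** Latency statistics are only meaningful for well
separated, moderate-intensity pulses. `filter_pulses()` therefore keeps a
pulse when (i) its onset-to-onset interval from the preceding pulse is at
least 200 ms, (ii) its power is at most 5 mW, and (iii) it does not belong
to a 40 Hz train (at that rate spiking failure dominates and latency loses
meaning). The interval rule is anchored at pulse onsets; since the retained
interpulse spacing (≥ 200 ms) exceeds the 20 ms analysis window, every spike
can be attributed to at most one pulse.

**Latency.** For each retained pulse, `first_spike_latencies()` takes the
time from onset to the first spike in the window (0, 20] ms — a spike
exactly at onset is not a response (latency must be positive), a spike
exactly at the window edge is. Trials without such a spike are failures.
`summarize_latency()` averages the non-failure trials only, since a
per-trial latency is undefined on a failure, and reports the fraction of
responding trials as the response probability.

**Decision rule.** `classify_optotag()` labels a cell *direct* when the
mean latency is below 4 ms **and** the response probability is at least 0.5;
*nonresponsive* when the probability is below 0.5; *indirect* otherwise.
The probability floor is a deliberate operationalization of "reliably
evoked": a spontaneously active cell at 2 Hz lands in a 20 ms window by
chance in only ~4% of trials, so 0.5 cleanly separates driven responses
from coincidences while tolerating synaptic failures. Spontaneous spikes
inside the window are *not* distinguished from evoked ones — the first-spike
rule makes no such distinction, and the probability floor absorbs the
resulting false positives. The floor is exposed in
`analysis_config(response_probability_min = )` because reasonable analysts
could place it elsewhere.

PSTHs (`compute_psth()`) use half-open 0.1 ms bins over the same 20 ms
window; they are descriptive and play no role in the decision rule.

## Electrophysiological typing

`burst_index()` counts interspike intervals at or below 6 ms and divides by
the total spike count. The phrase "spikes with a short ISI" is genuinely
ambiguous between counting intervals, spikes preceded by a short interval,
or all spikes participating in one; the interval-count convention is the
default and the participating-spike alternative is selectable
(`convention = "participating"`). Burst indices are only computed for
recordings with more than 50 spikes. Cells firing above 10 Hz during
exploration — or with a spike peak-to-trough under 0.4 ms when a waveform
annotation exists — are classified as interneurons and excluded from the
spatial group comparison.

## Spatial maps and metrics

Positions are LED midpoints; frames with a missing LED are dropped, never
interpolated (interpolation would manufacture dwell time in places the
animal may not have been). Speed is a central difference smoothed with a
0.25 s boxcar; samples at or below 1 cm/s, and the spikes nearest to them
in time, are excluded from all spatial quantities.

The arena is discretized into 2.5 × 2.5 cm pixels. Occupancy and rate maps
are computed by summing, over raw tracking frames and raw spike positions
respectively (not over pre-binned histograms), a 2D Gaussian kernel centered
on each sample:

$$z(x) = \sum_t w(|x - x_t|)\,\Delta t, \qquad
  r(x) = \frac{\sum_i w(|x - x_i|)}{z(x)}$$

with kernel SD σ = 1 pixel (2.5 cm). σ is interpreted in pixel units because
the formulas operate on the discretized grid; a different value can be set
via `analysis_config(kernel_sigma_px = )`. Two numerical conventions keep
the maps well behaved:

* the kernel is truncated at 4σ and renormalized per sample over the
  in-grid pixels it reaches, so the deposited mass is conserved *exactly* —
  the occupancy map always sums to the included tracking time and the rate
  map's numerator to the included spike count, with no leakage at arena
  edges (this is also what makes the occupancy-weighted mean of the rate map
  equal the observed mean rate);
* pixels occupied for less than 20 ms are masked: a rate estimate from
  almost no dwell time is noise.

Spatial information and sparsity follow the standard occupancy-weighted
forms over *valid* pixels, with the occupancy probabilities renormalized to
the valid set (an undefined rate cannot enter a sum):

$$I_\text{spike} = \sum_n p_n \frac{\lambda_n}{\lambda}
   \log_2\frac{\lambda_n}{\lambda}, \qquad
  \text{sparsity} = \frac{(\sum_n p_n\lambda_n)^2}{\sum_n p_n\lambda_n^2}$$

with $0\log 0 := 0$. The sparsity form is chosen so that the index lies in
(0, 1], equals 1 for spatially uniform firing, and 1/N when firing is
confined to one of N equally occupied pixels — i.e. *higher* sparsity means
*more diffuse* firing; the reciprocal reading of the same expression is its
inverse and would flip that interpretation. Both metrics are computed on
the 2D pixel maps; linearized maps are used only for display and stability.

## Linearization, laps, stability

The closed maze makes position effectively one-dimensional.
`fit_ellipse()` fits an ellipse to the trajectory by the direct
least-squares conic method (eigensystem under the ellipse constraint —
implemented in the package since no installed dependency provides it), and
`linearize()` maps each position to the arc length of its radial projection
(the intersection of the center-to-point ray with the ellipse). True
closest-point projection differs from radial projection by far less than a
2.5 cm bin for points within the 9 cm path of this low-eccentricity track,
so the simpler, always-defined projection is used and documented as an
approximation. Arc length and perimeter come from trapezoidal quadrature on
a 4096-node parameter grid (relative error ≪ 1e-6).

A *lap* is not defined by the experiment itself, so the package defines it
as one full perimeter of unwrapped excursion: the linearized coordinate is
converted to phase, unwrapped, and the excursion range divided by 2π. The
range (rather than the net displacement) is used so that an animal
alternating directions still accrues the laps it actually ran, while
back-and-forth dithering below a full circuit counts zero.

Linearized rate maps use 2.5 cm arc-length bins (matching the 2D pixel
scale), circular Gaussian smoothing (σ = 1 bin) of the occupancy and spike
histograms before division, and masking of empty bins.
`split_half_stability()` splits the recording at the temporal midpoint —
not by laps, so the two halves have equal observation time regardless of
running behavior — computes a linearized map per half with the ellipse
fitted to the whole trajectory, and correlates the two maps (Pearson) over
bins valid in both halves.

**Inclusion.** Spatial metrics enter group comparisons only for recordings
with more than 50 movement-filtered spikes and at least 3 laps. Note the
movement filter also shapes the overall mean rate entering λ; the unfiltered
whole-session mean rate is reported separately in the cell table.

## Group statistics

`compare_groups()` is a two-sided Wilcoxon rank-sum test: exact (full
permutation distribution of the rank sum via dynamic programming over
midranks, so ties are exact too) when both groups have fewer than 10
observations, and a tie-corrected normal approximation otherwise. The exact
two-sided p is `min(1, 2·min(P(W ≤ w), P(W ≥ w)))`. The test is implemented
in the package because the base implementation has no exact p-value under
ties; the tie-free branches are cross-checked against `stats::wilcox.test`
in the test suite, and the exact branch against brute-force enumeration.
Three-group latency comparisons use `stats::kruskal.test`, followed by
pairwise rank-sum tests with Bonferroni correction (the multiple-comparison
procedure is otherwise unconstrained, and Bonferroni is the most
conservative conventional choice). Histology annotations, when present,
cross-check the opto label; a direct responder annotated
histology-negative is surfaced as a conflict rather than silently resolved
in either direction.

## The synthetic cohort

The generator (`generate_cohort()`) emulates the statistical structure the
analysis assumes, with known ground truth:

* **Behavior** (`simulate_trajectory()`): a two-state run/pause process
  with gamma-distributed bout durations (shape 4; mean run 8 s, pause mean
  set so runs occupy 70% of time), Ornstein–Uhlenbeck forward speed around
  per-bout targets (log-normal around 12 cm/s, clipped to 5–30 cm/s; pauses
  crawl below 0.3 cm/s), occasional direction reversals (p = 0.15 per
  pause), and lateral jitter that evolves per centimeter traveled (so paused
  animals do not drift) bounded inside the 9 cm path. Tracking is rendered
  as two LEDs 3 cm apart at 25 Hz — a typical video rate, chosen here as a
  convention. Sessions default to 600 s of exploration followed by a
  1 Hz / 1 ms / 0.5 mW train of 50 pulses.
* **Place cells** (`simulate_place_cell()`): inhomogeneous Poisson spiking
  by thinning against λ(t) = baseline + gain·exp(−d(s, c)²/2w²) on the
  circular linearized coordinate, plus complex-spike bursts: each spike is
  promoted with probability 0.4 to a 2-spike burst at 3–5 ms intervals,
  which yields an expected burst index of 0.4/1.4 ≈ 0.29, the regime typical
  of CA1 pyramidal cells. A 2 ms absolute refractory period is enforced
  (without it, burst promotion could produce zero-ISI artifacts). Strongly
  tuned cells default to baseline 0.5 Hz, gain 6 Hz, field SD 10 cm; weakly
  tuned cells to baseline 1.3 Hz, gain 0.8 Hz, SD 15 cm — both around 2 Hz
  mean rate, so the two classes differ in spatial structure but not rate.
* **Light responses** (`simulate_opto_response()`): per pulse, an evoked
  spike with class-specific probability (direct 0.9; indirect 0.6 with
  optional facilitation per within-train pulse number; nonresponders never)
  at a latency drawn from a truncated normal (> 0.5 ms): direct
  2.5 ± 0.5 ms, indirect 7.5 ± 2.0 ms. The truncated normal reflects the
  unimodal, narrow latency histograms such responses show; the awake
  burst-evoking regime is available through an evoked-burst probability,
  whose value is exposed rather than asserted since burst probabilities per
  pulse are not established quantities.

The default study cohort pairs 26 strongly tuned nonresponders with 12
weakly tuned direct responders — the class coupling and group sizes of the
spatially analyzed CA1 population this package targets. A separate
150-cell benchmark (`opto_bench_cohort_spec()`) with direct / indirect /
nonresponsive thirds exercises the classifier alone.

**What passing tests show — and what they do not.** The generator
reproduces the *assumed* structure: Poisson variability, place tuning on a
circular coordinate, bursting, latency regimes with failures. Real
recordings additionally contain theta rhythmicity and phase precession,
rate remapping, slow drift and cell damage, tracking artifacts beyond
frame drops, and light-artifact contamination — none of which are modeled.
Recovery of ground-truth labels and group separations on synthetic cohorts
therefore validates the *implementation* of the analysis chain (and its
power under the stated effect sizes), not the biological claim itself.

## Problem sizes and numerical tolerances

The test suite exercises formula implementations against naive double-loop
oracles (1000 random maps, agreement to 1e-12), closed forms (uniform and
one-of-N maps, exact), kernel mass conservation (50 random trajectories,
1e-6 relative), exact rank-sum enumeration (1000 random instances, group
sizes ≤ 8), latency recovery (20 seeds × 50 trials, 0.15 ms), classifier
recovery (150 cells, ≥ 95%), and the full group-separation property (100
seeded 38-cell cohort runs: rank-sum p < 0.01 for information and sparsity
with the expected ordering, and higher stability in the tuned class, in at
least 95 runs). Sessions of 600 s at 25 Hz are the default generative
condition throughout; these sizes keep a full run of the suite to a few
minutes while leaving each statistical check comfortably powered.

## Known limitations

* Radial (not closest-point) ellipse projection; adequate for annular
  tracks, inappropriate for strongly eccentric or non-convex tracks.
* No spike sorting or light-artifact handling: spike times are taken as
  given, which matches single-cell (juxtacellular) recordings but not
  multi-unit extracellular data.
* No shuffling-based place-field significance test, no 2D field
  segmentation, no theta/phase analysis, no LFP support.
* The anatomical (layer-depth) component of molecular-class assignment is
  representable only as a histology annotation; it cannot be computed from
  the data this package sees.
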