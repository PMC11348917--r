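---
title: "Methods: quantifying retinal input specialization and visual tuning of dLGN interneurons"
author: "geniculate package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying retinal input specialization and visual tuning of dLGN interneurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geniculate)
```

# Scope

Inhibitory interneurons of the dorsolateral geniculate nucleus (dLGN) receive
convergent input from many retinal ganglion cells (RGCs). Two complementary
experimental views of these neurons motivate this package: rabies-based
monosynaptic tracing, which yields for each postsynaptic interneuron a
*cluster* of presynaptic RGCs that can be typed morphologically in flat-mount
retina, and in vivo two-photon calcium imaging, which yields visual response
properties (direction and orientation selectivity, suppression by contrast,
receptive fields) of the interneurons and their dendrites. The package
implements the quantitative machinery for both views — occupancy-based
specialization statistics, ChAT-band-referenced flattening and RGC typing,
tuning and receptive-field analysis, and dendrite-versus-soma
correspondence — together with a synthetic-data module that generates every
input kind with known ground truth so that each stage can be validated
without access to recordings.

# Specialization of presynaptic clusters

## The occupancy null

The central question for a traced cluster is whether its RGC *types* are a
random sample from the type distribution of all RGCs projecting to the
region, or a specialized subset. The test statistic is deliberately simple:
the number of **distinct** types among the $n$ classified presynaptic cells.
Under the null hypothesis the cells are i.i.d. draws from a reference
distribution $p$, and the distinct-type count $D_n$ follows the classical
occupancy distribution with
$$\mathbb{E}[D_n] = \sum_t \left(1 - (1-p_t)^n\right).$$
`occupancyNull()` estimates the mean and SD of $D_n$ by Monte-Carlo
simulation (one `rmultinom()` call per replicate set), as the original
analysis did; the closed form above is kept in the test suite as an
independent oracle, and the Monte-Carlo moments are required to agree with
it within three Monte-Carlo standard errors. The default replicate count is
$10^5$ (the source analysis does not state one); at $n = 50$ and 40 types
this costs well under a second and puts the Monte-Carlo error of the mean
near $0.006$ types.

The specialization score of a cluster with $D_\mathrm{obs}$ distinct types
is $Z = (D_\mathrm{obs} - \hat{\mathbb{E}}[D_n])/\hat{\sigma}(D_n)$, and
$Z < -2$ is the conventional specialization flag. For 40 equally frequent
types and $n = 50$ this yields the boundary of 25: at least 25 distinct
types are expected by chance, fewer indicate specialization.

## Reference distribution

When scoring real clusters the reference is not uniform but the weighted
mixture of the empirical type distributions presynaptic to thalamocortical
neurons (TCNs) and to interneurons,
$p \propto p_\mathrm{TCN} W_\mathrm{TCN} N_\mathrm{TCN} +
p_\mathrm{IN} W_\mathrm{IN} N_\mathrm{IN}$ with
$W_\mathrm{TCN} = 0.8$, $W_\mathrm{IN} = 0.2$ (prevalence of the two
populations) and $N_\mathrm{TCN} = 20$, $N_\mathrm{IN} = 96$ (mean
presynaptic cells per neuron). `referenceDistribution()` implements exactly
this mixture and normalizes it.

## Pooling experiments

`poolingExperiment()` reproduces the thought experiments on how the
granularity of the type classification moves the Z score: with 40 uniform
types and $n=50$, a cluster covering a 26-type subset scores only
$Z \approx -1.4$ (undetected), a 20-type subset $Z \approx -4.5$; after
pairwise pooling that respects the subset the 13 pooled observed types score
$Z \approx -5.0$, while pooling each subset type with a non-subset type
hides the specialization entirely ($Z \approx +1.4$). Two conventions for
the "observed" count are possible; the default takes the number of pooled
labels covering the *full* subset (which reproduces all four worked
numbers), and the alternative — distinct pooled labels within one simulated
draw — is exposed via `observed = "draw"`.

## Binocular randomness

`binocularRandomnessTest()` asks whether the contra/ipsi split of
presynaptic cells deviates from a binomial draw with $p_\mathrm{contra} =
0.87$ (the average contralateral fraction). The statistic, the absolute
contra-minus-ipsi difference summed over postsynaptic cells, is already
two-sided, so the Monte-Carlo p-value is its upper-tail probability at
matched totals, with the add-one convention
$p = (1 + \#\{\mathrm{sim} \ge \mathrm{obs}\})/(1 + n_\mathrm{reps})$ so
that p is never exactly zero. The test suite verifies 5% type-I error
under the null within $\pm 2\%$.

# Flat-mount flattening and RGC typing

## ChAT bands as a depth coordinate system

The two ChAT-positive starburst-amacrine plexi are stereotyped depth
landmarks of the inner plexiform layer. `detectBandProbability()` converts
a ChAT image stack into a band-membership probability stack; the default
detector is a classical per-column matched filter (Gaussian kernel of the
expected band width along z, rectified and normalized), and any learned
detector can be plugged in behind the same contract, since the original
analysis used a U-Net whose training annotations are not available.
`extractBandSurfaces()` finds, per column, the two strongest separated
peaks, smooths the two surfaces with a running median across xy, and
*refuses* to continue when columns are ambiguous (listing them; a manual
curation table can fill them in) or when the smoothed surfaces touch —
silent band swaps are treated as worse than an error.

`flattenStack()` then maps each column linearly so the OFF band sits at
relative depth 0 and the ON band at 1, resampling at steps of exactly
0.025. Ten strata of width 0.25 tile the depth range $[-0.625, 1.875]$,
with stratum $k$ centered at $0.25\,(k-3)$ so strata 3 and 7 coincide with
the bands. The invariance that matters — a voxel's stratum does not depend
on band curvature — is tested across curvature amplitudes on phantoms.

## Quantitative typing rules

The original classification was by expert inspection; the package makes it
quantitative with declared, configurable thresholds (these are design
choices, not reconstructions of unstated expert criteria):

* a stratum "counts" when it holds at least 10% of the cell's signal;
* *co-fasciculation* with band $k$ requires at least 25% of the cell's
  signal within $\pm 0.125$ of the band **and** at least 50% of that
  in-window signal on xy positions with above-threshold ChAT signal. (A
  50% in-window requirement, natural for mono-stratified cells, cannot
  hold simultaneously for both bands of a bistratified type-37 cell, which
  is why the default fraction is 0.25.)
* the JAM-B asymmetry index is $|\mathrm{soma} - \mathrm{arbor\ center\ of\
  mass}| / \mathrm{arbor\ radius}$, with 0.3 as the flag threshold;
* type 7 tolerates minor stratum-3 branches below 15%;
* type 4 requires stratum 4 to hold the majority of the signal — a
  majority rule rather than a dominant-set rule, because an arbor centered
  on stratum 4 unavoidably spills a little signal into the adjacent
  windows.

The rule cascade (37, 7, 12_asym, 12, 189, 89, 4, other) is deterministic
and total, and the functional tags follow stratification: strata 3–7 carry
transient, the outer strata sustained kinetics; strata 6–10 ON and 1–4 OFF
responses; types 37 and 7 are direction-selective; 12_asym is JAM-B. On
phantoms with nine cells of the seven canonical types, at least 90% of
calls must match ground truth end to end (detection → flattening →
profiling → typing).

# Calcium-imaging tuning analysis

## From movie to responses

`preprocessMovie()` removes the bidirectional line-phase offset, applies
rigid per-frame registration (correlation peak over integer shifts) and a
500 ms moving average. ROIs are found on the local-correlation image (mean
Pearson correlation of each pixel with its 8 neighbors): seeds at local
maxima above 0.3, grown while the correlation exceeds
$\max(0.5\,c_\mathrm{seed},\ c_\mathrm{bg} + 0.1)$ — the dependence on seed
and background correlation is stated by the source, the three constants are
declared defaults. Each ROI's local background is the five darkest pixels
within 15 µm, and its trace is background-subtracted.

`extractResponses()` computes, per grating stimulus (8 directions × 3
speeds), the baseline (median signal 1.75–0.25 s before onset), the
trial-median baseline-subtracted response filtered with the same 500 ms
window, and from it $P_i$ (maximum), $N_i$ (−minimum) and the
stimulus-period average. SNR is the largest absolute amplitude over the
baseline SD; $F_0$ is the smallest baseline of the 24 average responses
and is used for display only — no index depends on it (an additive offset
guards $\Delta F/F_0$ when the smallest baseline is non-positive).

## Selectivity and significance

The four indices are the circular-variance resultants
$$\mathrm{DSI} = \frac{\left|\sum_i P_i e^{i\vartheta_i}\right|}{\sum_i P_i},
\qquad
\mathrm{OSI} = \frac{\left|\sum_i P_i e^{2 i\vartheta_i}\right|}{\sum_i P_i},$$
with negative amplitudes set to zero first, and the same forms on $N_i$.
Preferred direction (orientation) is the (half) phase of the population
vector, rotated by the 20° angle between the eye's main axis and the
screen horizontal (the sign of the correction is configurable since only
its magnitude is documented). DSI is forced to zero when the
positive-response SNR is ≤ 2.5, DSI$_{neg}$ when the negative-response SNR
is ≤ 2.5. Per interneuron the speed evoking the maximum response is
selected, separately for positive and negative indices, ties toward the
slowest (longest, best-sampled) stimulus.

Significance comes from permuting whole trials across direction labels
within a speed (the within-speed choice matches the wording "across
stimulus orientations"; 1000 permutations by default, seeded) with
$p = (1 + \#\{\ge \mathrm{obs}\})/(1 + n)$. A practical caveat the
phantoms expose: with very few trials and near-binary response vectors the
permutation null becomes heavy-tailed (a shuffled arrangement that
concentrates the few large amplitudes on one label yields an index near 1),
so power requires graded tuning or realistic trial counts — the package's
end-to-end tests use 3–4 trials with von Mises concentration 2–4
accordingly.

A cell is suppressed-by-contrast (SbC) when strictly more than half of the
24 stimulus-period averages fall below baseline. The unique category is
assigned by the hierarchy DS > OS > DS$_{neg}$ > OS$_{neg}$ > SbC > broad
(DS requires DSI > 0.3 and $p<0.05$, and wins even when OS is also
significant; broad requires DSI < 0.15 and OSI < 0.15).

# Receptive-field mapping

Sparse-noise sessions flash 8° squares for 0.6 s with 0.6 s gaps over a
116° × 86° screen. Per position, trials are aligned at onset, interpolated
to 33 Hz, averaged, and smoothed over 150 ms; ON amplitudes are signed
extrema during the flash against the 200–75 ms pre-onset baseline, OFF
amplitudes between flashes against the pre-offset baseline, excluding
±75 ms around transitions to avoid filter artifacts. Significance uses the
spatial-structure statistic — the maximum correlation of the map with
itself shifted by one pixel in any of the 8 directions, computed on the
overlapping sub-grid with signed amplitudes — against $10^4$ permutations
of the single-trial amplitudes across positions (a trial's ON and OFF
amplitudes travel together). Significant maps are smoothed with a 3 × 3
running average (shrinking at borders, so no padding bias), and the
receptive field is the 8-connected above-half-max region containing the
maximum; area is the region size × 64 deg², position its intensity-weighted
center of mass, and ON-OFF cells are measured on the sum of both filtered
maps. Note a consequence of filtering first: a single hot pixel spreads
into an equal 3 × 3 plateau, so its half-max region is nine pixels, not
one. Retinotopic maps are Gaussian-weighted averages (σ = 75 µm within a
300 × 300 µm mask) of the per-cell azimuth/elevation values.

# Dendrite-versus-soma correspondence

Dendritic compartments are compared to their soma through the
16-dimensional response vector (8 positive + 8 negative amplitudes) at the
speed evoking the soma's maximum response; Pearson correlation per
compartment, Euclidean inter-ROI-center distance (a lower bound on path
length), 50 µm bins for summary curves, and a mono-exponential decay
$y = \Delta e^{-x/\lambda} + y_0$ fitted by Levenberg–Marquardt least
squares (`minpack.lm::nlsLM`) with multi-start initialization over a grid
of length constants and λ bounded positive. Flat profiles are returned as
degenerate fits flagged non-identifiable rather than as errors. Recovery is
verified at σ = 0.02, n = 200: λ within ±15% in at least 9 of 10 seeded
replicates. The per-compartment SNR > 2.5 gate is applied before inclusion.

# The synthetic-data module

The generators are first-class, tested code, and their defaults encode the
study conditions: clusters draw types i.i.d. with contralateral probability
0.87; the retina phantom renders two parallel smoothly undulating band
surfaces (Gaussian z-profiles) plus radial dendrite polylines placed at the
requested strata *via the true surfaces*, with an asymmetry flag confining
rays to a half-sector for JAM-B-like arbors; the grating generator drives
von-Mises-tuned cells (doubled angle for OS, negative-going for the
suppressed variants, activity dips for SbC) through a single-exponential
indicator kernel (default 1.5 s, a slow indicator) into footprints plus
i.i.d. Gaussian noise, with dendritic compartments sharing the soma tuning
scaled multiplicatively by attenuation (noise and baseline are not
attenuated) — and fluorescence clamped at zero, since suppression cannot
push a fluorescence signal below zero; the sparse-noise generator evokes
transient ON/OFF responses with Gaussian spatial weight. The flash-evoked
transient defaults to a fast 50 ms alpha kernel so that an ON response has
decayed before the pre-offset baseline window; with a slow kernel an
ON-only cell would *genuinely* leave spatially structured amplitudes in
the OFF window, which is a property of slow indicators rather than a flaw
of the mapping procedure.

What the phantoms deliberately do not emulate: optics and PSF, scan or
motion artifacts beyond rigid jitter, behavioral covariates, overlapping
arbors requiring instance segmentation, and realistic noise spectra
(recordings' amplitude and noise statistics are not published, so noise
levels are free parameters documented in the configs). Passing tests
therefore demonstrate the correctness of the *procedures* on data whose
generative structure matches the assumed response models, not performance
on real recordings.

Seeds are mandatory throughout; every stochastic function takes one, all
randomness in a call flows from it, and the pipeline driver expands a
single global seed into deterministic per-stage child seeds so stages can
be rerun independently.

# Problem sizes used in the shipped tests

The test suite runs entirely on synthetic data at sizes chosen to exercise
every code path with comfortable margins: occupancy nulls at $2\times10^4$
replicates (Monte-Carlo SE ≈ 0.014 types, against the ±0.25 assertion
tolerance); calibration suites at 500 simulated sessions with 199
permutations/shuffles each; movie phantoms of 24–34 px and 3–4 trials at
5 Hz; retina phantoms of 64 px × 36 planes with nine cells; receptive-field
grids of 8 × 10. The acceptance script uses $10^5$ replicates. These sizes
reproduce the printed specialization numbers to well within their
tolerances while keeping the whole suite in the low minutes.

# Known limitations

* The classification thresholds (dominance 10%, co-fasciculation 25%/50%,
  asymmetry 0.3, minor-branch 15%) are declared defaults standing in for
  expert judgment; on real stacks they should be tuned against curated
  examples.
* The z-offset between imaging channels is exposed only as an optional
  shift parameter; no estimation procedure is provided.
* The trial-permutation significance test loses power for near-binary
  response vectors at very low trial counts (see above), and the
  receptive-field shuffle test shares the usual 5% false-positive rate —
  single-session polarity calls near threshold should not be
  over-interpreted.
* `matchRois()` performs rigid alignment only; non-rigid warping across
  days is out of scope.
* Group-level statistics on pipeline outputs (rank tests, contingency
  tests, multiple-comparison corrections) are intentionally left to the
  standard R functions.
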