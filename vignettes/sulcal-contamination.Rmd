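---
title: "Cross-sulcus signal contamination under volumetric and surface smoothing: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-sulcus signal contamination under volumetric and surface smoothing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it simulates, which
parameters matter, and why the open design choices were resolved the way
they were. Everything quantitative stated here is computed by the test
suite or by `scripts/acceptance.R`; nothing is quoted from elsewhere.

## The problem being modelled

Functional MRI analyses smooth their data spatially. When smoothing is
performed in the 3D volume, the kernel is blind to cortical topology: two
banks of a sulcus a few millimetres apart exchange signal even though they
belong to different functional systems separated by centimetres of cortical
sheet. The package builds a synthetic sulcus in which this contamination is
fully known and measurable, and implements both the volumetric pipelines
that exhibit it and the surface pipeline that avoids it.

## The phantom

`build_phantom()` extrudes a 2D cross-section along the sulcus axis. The
cross-section consists of a flat precentral crown, a vertical anterior
bank, a semicircular fundus of radius `bank_gap_mm / 2`, a vertical
posterior bank, a flat postcentral crown, and the anterior wall of a
second (postcentral) sulcus, giving five region labels. The defaults —
`fold_depth_mm = 18`, `bank_gap_mm = 4` — place the two seed vertices on
the opposing sulcal lips exactly 4 mm apart in 3D and
2·(18 − 2) + 2π ≈ 38.3 mm apart along the mesh. The along-surface target
of ≈ 40 mm is treated as a native-mesh design goal with a ±3 mm band; the
semicircular fundus is what pulls the value slightly below 2·depth + gap.
A flat-sheet limit (`fold_depth_mm = 0`) exists for testing, where
geodesic and Euclidean distances coincide.

Geodesics are shortest paths on the edge graph with Euclidean edge
weights (Dijkstra via `igraph`). At the default 1 mm edge length the graph
geodesic overestimates the exact polyhedral geodesic by under 5 %, which
is inside every tolerance used downstream; the union-jack triangulation
(quad diagonals alternating by parity) keeps one-ring neighbourhoods
isotropic, which matters for the surface smoother below.

The companion voxel grid is isotropic (`voxel_mm = 3`), aligned so that a
voxel boundary lies on the sulcal midplane, with a two-voxel margin. With
a 4 mm gap and 3 mm voxels the two banks then never share a voxel: every
cross-bank effect measured by the pipelines is attributable to smoothing
kernels or to trilinear interpolation, never to label ambiguity. Voxels
containing mesh vertices are `cortex`; the one-voxel shell around the
ribbon is split into `white` (inside the sheet) and `csf` (outside,
decided by the outward normal at the nearest vertex); everything else is
`background` and carries no signal.

Inter-subject anatomical variability is modelled, when enabled, as a
per-subject rigid transform (uniform translation up to `translate_mm`,
rotation up to `rotate_deg` about a random axis) whose exact inverse is
stored, so "normalisation" of volumes is an exact rigid resampling and
surface correspondence across subjects is the identity on vertex indices.
This deliberately reproduces the structural advantage of surface-based
analysis: vertexwise group statistics never pay a resampling cost, while
volume normalisation must interpolate.

## Signal simulation

**Haemodynamic response.** A canonical double-gamma:
gamma-density(shape 6, scale 1) minus one sixth of
gamma-density(shape 16, scale 1), peak-normalised. The response is zero at
t = 0 and peaks near 5 s. The specific shape is a convention; only its
smoothness and latency matter for the contamination questions.

**Event designs.** `make_periodic_design()` places one event per whole
`period` contained in the run (floor(run/period) events at 0, period, …),
so every event's cycle fits the acquisition. `make_task_design()` draws
inter-stimulus intervals uniformly from a range; `make_alternating_design()`
alternates two conditions strictly, with the starting condition seeded —
strict alternation was chosen over randomised interleaving because it
fixes per-condition event counts, which stabilises per-condition contrast
variance; the randomised alternative would only add design noise.

**Background noise.** `noise_model()` produces temporally AR(1) noise
(default coefficient 0.3), a per-voxel linear drift with standard
deviation 1 % of sigma over the run, and spatial correlation imposed by
smoothing the innovation field at 6 mm FWHM (two voxel widths) before
rescaling to unit per-voxel variance. The spatial term exists because real
resting-state BOLD fluctuations are spatially coherent; with voxelwise
independent noise, surface smoothing would average the background away
almost entirely and every surface result would look implausibly clean.
Background-compartment voxels stay exactly zero.

**Injection.** `inject_hrf_signal()` adds
amplitude · weight(voxel) · (boxcar ∗ response) sampled at the TR.
Vertex-level ramp weights (linear in geodesic distance, 1 at the centre,
0 at `radius_mm`; the linear shape is the simplest curve through the two
stated endpoints) are converted to voxel weights as the mean over each
voxel's vertices, so the injected field is voxel-quantised — and the
vertex-level ground truth used by the overlap metrics is accordingly
"every vertex inside a signal-carrying voxel". The injected amplitude
default for the experiments is 3 background standard deviations, a
contrast-to-noise ratio representative of robust primary somatosensory
responses; it keeps single-subject detection comfortable without being
trivial once 6–12 mm kernels have diluted the signal over the small
phantom.

## The connectivity generator and its calibration

Each subject receives three pure signals on a 210-volume, TR 2.52 s grid:
`s1` — a 0.05 Hz sinusoidal carrier with random phase mixed with a 20 %
white-noise portion (amplitude weights 0.8/0.2 on standardised
components); `s2c` — built on the same carrier; `s2u` — built on an
independent-phase carrier. `s1` is scaled into the postcentral ROI mean by
a multiplicative amplitude schedule (variance-matched start, ×1.1 steps)
until the combined signal correlates at least 0.95 with the pure signal,
the smallest amplitude on the schedule being kept.

The design values of the experiment are the correlations of the *final
combined* postcentral signal with the two precentral signals: 0.82 for
the correlated pair and 0.04 for the uncorrelated pair. The generator
realises them by construction: after the insertion loop returns the
achieved combined~pure correlation r1, `s2c` and `s2u` are
correlation-pinned to `s1` at rho = design/r1 (an exact Gram–Schmidt
construction on the sample), so the expected combined~s2c correlation is
exactly the design value, with residual spread contributed by the
background. Subjects whose achieved correlations leave the bands
[0.80, 0.84] (correlated) or |r| in [0.02, 0.06] (uncorrelated) are
resampled with fresh signal noise, with a bounded retry budget; in
practice one or two draws suffice. The alternative — fixing the mixing
weights and hoping the bands emerge — does not work: the two natural
readings of "20 % noise" bracket the band from above (≈ 0.94 expected)
and below (≈ 0.80), so the band must be a design target, not an accident.

The two precentral patches (3 mm geodesic discs, like the postcentral
ROI) straddle the motor seed at ±4 mm along the sulcus axis, directly
across the 4 mm gap from the postcentral ROI. This "directly across the
sulcus" placement is the configuration the contamination question is
about; pushing the patches further along the sulcus weakens volumetric
mixing quadratically in the Gaussian exponent.

## Smoothing operators

**Volume.** Separable 1D Gaussian convolutions per axis, kernel sampled at
integer voxel offsets, truncated at 4 sigma, renormalised; whole-sample
reflective boundaries (so constants are fixed points; mass is conserved
while the kernel stays on interior support). `fwhm = 2·sqrt(2 ln 2)·sigma`
throughout.

**Surface.** Iterated one-ring averaging: each step replaces a vertex
value by a convex combination of itself (weight 1 − lambda) and its
neighbour mean. One full-mixing step contributes a per-axis kernel
variance of mean(edge length²)/2 at a vertex; the number of steps and
lambda ≤ 0.5 are chosen so the step variances sum exactly to sigma². By
the central limit theorem the iterated kernel is near-Gaussian; on a
regular planar mesh a delta smoothed at 9 mm FWHM reaches half its peak
at 4.5 mm ± 10 %, which the tests verify against the closed-form 2D
Gaussian, in both axis and diagonal directions (this is where the
union-jack triangulation earns its keep — a single-direction diagonal
split gives a visibly anisotropic kernel). The scheme preserves
constants, obeys the maximum principle, and cannot cross disconnected
components.

**Volume-to-surface mapping.** Five trilinear samples along the vertex
normal over ±1.5 mm (half the ribbon thickness; the sampling depth and
count are declared defaults, not inferred from any reference
implementation). `abs_max` keeps the sample of largest magnitude with its
sign, ties resolved toward the inmost sample; `weighted_mean` uses
Gaussian weights equal to 1 at the centre and 0.5 at the segment ends.
Samples leaving the grid are clamped with a warning. Note that trilinear
interpolation reads *voxel-centre* values: a sample close to the sulcal
midplane legitimately mixes in the opposite bank's voxel. This is a real
partial-volume pathway, not an artefact, and it is why even the surface
connectivity pipeline shows some residual inflation.

**Surface-to-volume.** Each cortex voxel receives the mean of its
vertices' values; other voxels zero.

## GLM, TFCE and permutation inference

First-level fits are ordinary least squares per element with a task
regressor per condition, an intercept, and an optional mean-centred linear
drift; t = cᵀb̂ / sqrt(ŝ² cᵀ(XᵀX)⁻¹c) with dof = n − rank(X). Zero
residual variance yields a signed-infinity sentinel and a flag. The group
stage is a one-sample t across subjects (dof = n − 1).

TFCE integrates extent^0.5 · height² · dh over thresholds up to each
element's value, with dh = max|value|/100 per map; the discrete sweep is
implemented in C++ with a union-find over descending thresholds and is
tested against a literal threshold-sweep oracle. The step count trades
accuracy of the closed-form limit (an isolated unit-value element
enhances to 1/3 as dh → 0) against cost; at 100 steps the relative error
of that limit is below 1 %. Negative values are enhanced on the negated
map and returned with their sign. Volume adjacency is 26-connectivity;
surface adjacency is the mesh edge graph.

Familywise error is controlled by sign-flipping whole subjects: the null
is the distribution of the maximum absolute TFCE statistic over elements,
and corrected p-values are (1 + #{null ≥ observed})/(n_perm + 1), which
is exactly valid for symmetric errors. All distinct flips are enumerated
when 2^n does not exceed the requested count (with a warning). Elements
with zero across-subject variance are excluded from the null maximum and
reported at p = 1. Alpha follows the study conventions: 0.01 for the
task-style analyses, 0.05 for the injected-response experiment. Type-I
error calibration is verified by simulation (50 pure-noise cohorts of 12
subjects, 200 permutations each, on a reduced phantom); with 50 binary
replicates the familywise rate estimate itself carries a binomial
standard error of about 0.03, which is the resolution at which the
nominal level can be checked at this problem size.

## Pipelines

Approach 1 (volume, standard order): normalise the time series, smooth in
the volume, fit the GLM, group inference on voxels. Approach 2 (volume,
GLM first): fit in native space, normalise and smooth the effect maps,
group inference. With zero jitter and no smoothing the two coincide
exactly (OLS is linear in the data), which the tests assert. Approach 3
(surface): fit in native space, map effect maps to the subject surface
with `abs_max`, smooth along the template mesh, group inference on
vertices.

The connectivity pipelines follow their stated orders strictly, and each
result records the executed step order so order fidelity is testable:
volume — normalise, smooth 9 mm, band-pass 0.01–0.1 Hz, regress out the
mean CSF signal, extract ROI means; surface — band-pass, CSF regression,
map to the surface (weighted mean) then smooth 9 mm on the surface,
extract vertex-ROI means. The band-pass is zero-phase frequency-domain
masking with raised-cosine edges two bins wide; filter choice moves
correlations by a few hundredths, which is why it is pinned down here.
The surface mapping and smoothing are implemented as two sequential steps
(map, then smooth) rather than a fused resampling.

## Evaluation

"Overlap accuracy" is the Jaccard index of the detected and true masks;
Dice, precision and recall are always reported alongside, since the
choice among them is a convention. The ground-truth masks are the
voxel-quantised injection support (volume: masked voxels with positive
amplitude; surface: vertices inside such voxels). Region-wise counts
assign each cortex voxel the majority region of its vertices. The
FWHM-trend regression is OLS of counts on kernel size plus region
indicators, per approach.

The finger experiment places two sources 5.8 mm apart along the
postcentral bank — the printed separation of neighbouring finger
representations — under strictly alternating stimulation, and runs with
per-subject jitter (translate 1.5 mm, rotate 2°) by default, because the
comparison it operationalises is precisely the registration advantage of
surface analysis; with a shared, perfectly aligned anatomy the idealised
volume pipeline has no resampling cost to pay and the comparison is
degenerate. Source resolution is declared when both conditions have
suprathreshold vertices, the winner-take-all partition of their union
keeps both labels, and each label's peak vertex lies nearer its own seed
than the other's.

## Problem sizes and determinism

The default phantom is a 14 × 14 × 10 grid of 3 mm voxels around a
2170-vertex mesh; experiments use 19 subjects, 200 volumes (injected
response), 210 (connectivity) or 410 (task), TR 2.52 s, and 1000
permutations. These sizes make every experiment in the package rerunnable
in minutes on a single core while keeping all the qualitative structure;
the type-I calibration uses a reduced sheet and 200 permutations for the
same reason. All randomness flows from explicit integer seeds through a
scoped generator that never touches the global RNG state, so every
cohort, experiment and report is a pure function of (configuration,
seed).

## Limitations

The phantom idealises aggressively: a single sulcus, uniform 4 mm gap,
rigid-only inter-subject variability with an exactly known inverse, no
slice-timing/realignment/distortion surrogates, no physiological noise,
and identical injected amplitudes across subjects. Passing results
therefore demonstrate properties of the *pipelines* — where kernels do
and do not move signal, how inference behaves — not claims about any
particular real dataset. Counts of suprathreshold elements depend on the
phantom's size and the injected contrast and are meaningful as orderings
and trends, not as absolute numbers. The graph geodesic slightly
overestimates true surface distance; the surface smoother's kernel is
Gaussian only asymptotically; and the weighted-mean mapper inherits a
genuine partial-volume pathway from trilinear interpolation, which should
be kept in mind when interpreting residual surface-pipeline inflation.
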