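---
title: "Methods: fuzzy local-information segmentation and swarm-driven feature selection"
author: "brainseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fuzzy local-information segmentation and swarm-driven feature selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainseg)
```

# Overview

`brainseg` implements a complete desk-scale analysis stack for 2-D brain-MRI
slices: ground-truthed phantom simulation, preprocessing, an intuitionistic
fuzzy c-means segmentation engine with a local spatial-information penalty
(LWIFCM) whose initialization and key parameters are searched by a chameleon
swarm optimizer, a binary chaotic transient-search wrapper feature selector,
a layer-shape calculus for a channel-expansion residual attention
classifier, and the associated evaluation metrics. Everything runs on
synthetic phantoms, so every stage is testable against known ground truth
without any external imaging data.

This vignette documents the models, the parameters that matter, the places
where the underlying method descriptions were ambiguous and a concrete
design had to be chosen, and what the synthetic experiments do and do not
demonstrate.

# The phantom generator

`generate_phantom()` draws an axis-aligned elliptical brain (semi-axes 0.8
and 0.7 of the half image size) partitioned into concentric tissue bands at
configured intensities, a tumor disc with a low-order sinusoidal boundary
perturbation placed uniformly at random wholly inside the brain, and a
bright skull ring separated from the brain by a dark gap (so that
threshold-based skull stripping faces a realistic, but solvable, topology).
Two corruptions emulate MRI physics:

* **Bias field** — a unit-mean multiplicative surface built from two
  low-frequency cosines with random phase, scaled so the peak deviation
  equals `bias_amplitude`. This mimics coil inhomogeneity: smooth,
  multiplicative, and slowly varying.
* **Rician noise** — magnitude noise `sqrt((x + sigma*g1)^2 + (sigma*g2)^2)`
  with standard normal fields `g1`, `g2`, the exact magnitude-MRI noise
  model. On zero-intensity background it reduces to a Rayleigh field with
  mean `sigma * sqrt(pi/2)`, which the tests verify against the closed form.

What the phantom does **not** model: anatomy (gyri, ventricles, partial
volume), 3-D structure, multi-modal contrasts, and motion or ghosting
artifacts. Passing phantom tests therefore demonstrates algorithmic
correctness and noise robustness in a controlled regime, not clinical
performance.

The feature-table generator emulates the tabular "shape/texture/intensity"
descriptors a wrapper selector operates on. Each informative column is a
*class marker*: one class (classes are covered cyclically in shuffled
order) is shifted `effect_size` feature standard deviations away from the
rest. Markers are complementary by construction — dropping the only marker
of a class removes the ability to separate that class — which is the
realistic structure of radiomics panels and makes "informative" operationally
meaningful for a selector. An earlier draft gave every informative column
the same graded class means; those columns are then collinear copies of one
signal, and any two of them saturate the achievable accuracy, which makes
full recovery of the informative set impossible for *any* selector that
penalizes subset size. The default is four classes, matching the
tumor-typing setting (three tumor types plus "no tumor").

# Preprocessing

* **Skull stripping** (`strip_skull`): Otsu threshold, binary closing (disc
  radius 3), largest connected component, erosion (disc radius 2). On
  256-pixel phantoms the recovered mask overlaps the true brain mask with
  IoU above 0.9; the erosion intentionally trades a thin boundary band for
  robustness against leakage into the skull ring.
* **Median filter** (`median_filter`): exact odd-window medians with
  mirror-reflection padding. It is idempotent on piecewise-constant inputs
  after at most two passes, which the tests assert.
* **ACCLAHE** (`acclahe`): contrast-limited adaptive histogram equalization
  in which each tile's clip limit is scaled by that tile's normalized
  histogram entropy, `clip(tile) = base_clip * (0.5 + H/log2(nbins))`.
  The adaptive rule directs equalization headroom to busy tiles (tissue
  interfaces, tumor boundaries) while flat tiles — air, uniform tissue —
  get a tighter clip and amplify less noise. Whether the clip adapts per
  tile or globally was an open design point; the per-tile rule is this
  package's documented choice and is exposed in the configuration.
  Enhancement is quantified by `enhancement_metrics`: PSNR in dB and RMS
  contrast ×100 (RMS contrast is itself a documented choice, as "contrast"
  has no universal definition).

# The clustering engine

## Intuitionistic memberships

Plain fuzzy c-means represents each pixel by memberships `u_ij` summing to
one over clusters. The intuitionistic extension adds a non-membership
`gamma = (1 - u^alpha)^(1/alpha)` (a Yager complement) and a hesitation
degree `pi = 1 - u - gamma`, with `u + gamma + pi = 1`. The uncertainty
parameter `alpha` must lie in `(0, 1]`: for `alpha > 1` the complement makes
`u + gamma > 1` and the hesitation negative, violating the defining
constraint, so the package rejects such values (default `alpha = 0.85`).
The modified membership is `u* = u + pi`, column-renormalized — the
standard intuitionistic construction; the hesitation mass is folded back
into the membership so the weighted center update stays well defined.
At `alpha = 1` the hesitation vanishes and the whole engine reduces
*exactly* to plain FCM, which is enforced by an oracle-equivalence test
against an independently coded FCM at tolerance 1e-10.

## Local spatial information

Two spatial quantities make the clustering noise-aware:

* the **local information weight** `k_j = (sigma_j^2 + rho)/(mean sigma^2 +
  rho)`, the ratio of the intensity variance in the window around pixel j
  to its image-wide mean. `rho` (default 1e-3 intensity²) stabilizes the
  ratio on flat images. High-variance pixels (noise impulses, edges) get
  `k > 1`, flat interiors `k < 1`.
* the **spatial disagreement penalty** `G_ij = sum over neighbors r of
  1/(1 + d_jr) * (1 - u_ir)^m * (x_r - v_i)^2` — the canonical fuzzy
  local-information factor. It is zero when the neighborhood crisply agrees
  with cluster i or when neighbors sit exactly on the center, and grows
  when a pixel's neighborhood contradicts an assignment.

The neighborhood is a square window of half-width `window_radius` (default
1, i.e. 3×3) with mirror padding. The penalty enters the membership update
through the effective distance `d^2 + k_j * G_ij`, so an isolated impulse
is pulled toward the cluster its neighborhood supports; with the local term
disabled the update is the textbook FCM formula. The objective records
`sum u*^m d^2 + sum pi exp(1 - pi) + sum k_j G_ij`; the data term uses the
exponent `m` for consistency with the center update (the source material is
ambiguous between `u*` and `u*^m`; the exponent form is the default and the
linear form is switchable).

Two practical consequences, both visible in the tests: the spatial penalty
*smooths boundaries*, so on noise-free piecewise-constant phantoms it is
turned off (there is nothing to denoise and exact boundaries are
recoverable); and its benefit shows under impulse noise, where the paired
phantom trials show higher tumor Dice with the term enabled. Small
structures near the window scale (a tumor a few pixels across) can be
eroded by the penalty — the variance-ratio weight `k` is largest exactly at
boundaries — so the phantom studies use 128-pixel slices where the tumor
radius is comfortably above the window size.

## Degenerate cases

Zero distances give crisp columns (ties to the lowest cluster index); a
cluster that loses all weight is re-seeded at the worst-fit point with a
warning; coincident initial centers are rejected.

# The chameleon swarm optimizer

`csa_minimize` is a bound-constrained continuous minimizer with three
phases per iteration: a prey-search update attracted toward the personal
and global bests (or, with probability `P`, a random exploration step whose
scale `rho = delta * exp(-alpha_decay * t/R)` decays over iterations); an
eye-rotation step applying a random planar (Givens) rotation of each
position about the swarm centroid; and a velocity-based launch
`x <- x + (v_new^2 - v_old^2)/(2y)` with inertia-weighted velocity and the
acceleration `y = 2590 (1 - 1/r)`. Since `y` is zero at the first
iteration, the launch is skipped there — the published recurrence leaves
that division unguarded. Several constants the method names but never
values (`p1`, `p2`, `P`, `delta`, `alpha_decay`, `beta`) default to
`2.0, 1.8, 0.1, 1.0, 3.5, 3.0` and are all configurable. Positions are
clipped to the box after every phase and the best-so-far never worsens
(elitism), which the tests assert on every run. On the 3-D sphere function
the optimizer reaches 1e-2 well within a 30×200 budget.

# Swarm-driven segmentation

Fuzzy segmentation quality hinges on the initial centers and on
`(alpha, m)`. `segment_image` encodes a candidate as
`[v_1..v_c, alpha, m]`, bounded by the observed intensity range and the
configured parameter ranges, and lets the swarm minimize a fitness computed
by running LWIFCM from the candidate for a capped number of iterations
(default 10; full convergence inside the fitness loop would be wasteful).

**Fitness scale.** The candidate's own final objective cannot serve as the
fitness when `m` is part of the search: the data term `sum u^m d^2` shrinks
with growing `m` for *any* centers, so a raw-objective search drifts to the
upper `m` bound regardless of fit quality (observed empirically: the tumor
center is dropped entirely). The default fitness therefore runs the
candidate's dynamics but scores the *centers it reaches* with a
fixed-reference FCM objective at fuzzifier 2 — a scale common to all
candidates. The literal raw-objective fitness remains available via
`segmentation_config(fitness = "objective")` for comparison.

The winner is refined by a full LWIFCM run to convergence; labels are the
argmax of the modified memberships. Cluster labels are arbitrary, so all
reported overlap scores go through `match_labels`, a greedy maximum-overlap
one-to-one assignment, making every score label-permutation invariant.
`c` defaults to 4 (background, two tissues, tumor).

Paired phantom trials (25 seeds, 64-pixel slices, small swarm budgets)
verify the ensemble's premise: swarm-seeded runs reach a final objective at
least as good as random initialization in over 80% of trials.

# Wrapper feature selection

The selector walks a population of continuous positions in `[-4, 4]^N`
(sigmoid activations then span roughly 0.02–0.98). Per iteration `l` the
transient coefficients are `z = 2 - 2 l/L_max`, `T = 2 z r2 - z` in
`[-2, 2]`, and `C1 = k z r3 + 1` (the printed form ends in a bare "l",
read as "+1" with a fresh random stream `r3`). The position update follows
the switched-circuit transient: an exponential decay toward the best
solution, or an oscillatory exploration branch, chosen by `r1 < 0.5`.
The draws `r1`, `r2`, `r3` are made **per dimension**: the published
recurrences do not state whether they are scalar per individual or
elementwise, and the scalar reading moves every coordinate along the same
transient, collapsing the population onto a line through the best position
— in calibration runs the search then stalls below the fitness of the known
informative subset. Per-dimension draws restore coordinate-wise diversity
and let the selector reach the exhaustive-search optimum on small problems.

Chaotic logistic-map streams (`x_{t+1} = 4 x_t (1 - x_t)`) can replace the
uniform draws for population initialization and for `r3`, both enabled by
default; the map's orbit is deterministic given the seeded starting value,
so runs remain reproducible.

Positions are binarized by `sigmoid(x_d) > r_d` with per-dimension uniform
thresholds; empty masks are resampled and, as a last resort, the
maximum-sigmoid bit is forced. The fitness of a mask is
`w1 * Acc + w2 * (1 - n/N)` with `w1 = 0.6`, `w2 = 0.4`, where `Acc` is the
stratified k-fold cross-validated accuracy of a 5-nearest-neighbour
classifier on the selected columns. The printed fitness adds `w2 * n/N`,
which rewards *keeping* features and contradicts the selector's stated
purpose; the sign-flipped form is the default and the literal form is
available via `fitness_ratio_sign = "literal"`. The classifier's
tie-breaking is seeded from the mask itself, making each mask's fitness a
pure function of the mask and fold assignment — this is what allows an
exhaustive oracle over all `2^N - 1` masks to be compared exactly against
the search on 10-feature problems.

# The architecture calculus

`propagate_shapes` is a pure integer calculus over an ordered layer list:
the channel-expansion residual block (stride-2 entry max-pool, three
parallel same-padded max-pools with windows 3/5/7 concatenated, plus the
entry tensor tiled threefold along channels) maps `(C, H, W)` to
`(3C, H/2, W/2)` with no parameters; the attention block is
shape-preserving; the fusion block pools shallow taps to the deepest tap's
spatial size, projects them 1×1 to its channel count and concatenates. The
printed configuration — stem conv 3×3 stride 2 with 16 filters, 2×2
max-pool, three expansion+attention stages, fusion, global average pool,
fully connected and softmax — reproduces every published tensor size from a
`(3, 416, 416)` input, which is a frozen golden test. The prose description
mentions two downsampling layers while the shape table requires three
spatial halvings across the expansion blocks; the shape table wins, and
each expansion block downsamples at entry. The printed softmax width (38)
does not match the four-class tumor task; the width is configurable and
the printed value is the golden-test default, surfacing rather than hiding
the inconsistency.

The attention block's channel branch transforms pooled channel statistics
by the *reciprocal* of the Gaussian density with moments estimated from the
vector itself — values far from the channel mean are amplified — then
squashes by a sigmoid; the spatial branch convolves stacked channelwise
mean/max maps. The literal additive combination is the default; a
multiplicative gating variant is a configuration switch. Forward passes use
seeded He-scaled random weights, so `extract_features` is a deterministic,
untrained multiscale feature bank: on phantoms its vectors separate tumor
intensity differences from mere noise realizations in the majority of
seeded trials, which is exactly the property a downstream selector needs.
The study condition for that check is a conspicuous contrast — tumor
intensity 0.8 versus 0.5 at tumor radius 0.3 of the brain radius under 2%
Rician noise; an untrained bank has no business resolving subtler contrasts
over a global average pool, and the test documents that boundary rather
than overstating it.

# Numerical choices and problem sizes

* Convergence: maximum center shift below `tol` (default 1e-5), iteration
  cap 100.
* Phantom studies run at 128 pixels (64 for the many-trial paired studies),
  swarm budgets of 5–10 chameleons × 6–15 iterations, and
  capped 6–10-iteration fitness runs; these sizes give stable statistics
  while keeping the full suite comfortably reproducible on a laptop-class
  single core.
* Impulse-noise study condition: 2% of pixels set to full intensity. At
  this level the local term's correction dominates its boundary smoothing;
  at much higher impulse rates the highest-intensity cluster must model the
  impulses themselves and every intensity-only method degrades.
* The plain-FCM objective is asserted non-increasing; the LWIFCM objective
  is recorded per iteration and monitored (the spatial penalty enters the
  membership update, so strict monotonicity is not guaranteed theory-side).

# Known limitations

* Intensity-only clustering: no texture or multi-channel features inside
  the segmentation engine.
* The spatial penalty erodes structures near the neighborhood scale.
* The untrained feature bank is a stand-in for a trained network; it
  demonstrates the plumbing and multiscale structure, not learned
  representations.
* All evaluation is on synthetic phantoms; no claim is made about
  performance on clinical MRI.
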