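---
title: "Clonal analysis of combinatorially labeled cortical cells: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clonal analysis of combinatorially labeled cortical cells: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonecortex)
```

## The problem

Combinatorial fluorophore labeling (CLoNe-style lineage tracing) marks each
labeled progenitor with a random subset of fluorophores at random expression
levels; every cell of the resulting clone inherits that combination. Reading
a clonal map out of a multichannel confocal image therefore requires four
computational steps, which this package implements end to end:

1. **Segmentation** of each 8-bit channel by histogram-based multi-level
   thresholding, with the number of thresholds chosen by PSNR;
2. **Cell extraction** (centroid + per-channel mean intensity);
3. **Decoding**: quantization of mean intensities into discrete levels,
   concatenated into a per-cell *code*; cells sharing a code within a tissue
   section form one clone;
4. **Statistics**: clone-size frequencies, pairwise distances of clonally
   related vs unrelated cells stratified by cortical layer, rank tests,
   Sidak-corrected layer-count comparisons, laminar contribution fractions.

Because raw microscopy data of this kind are rarely shareable, the package
also contains a fully seeded synthetic generator that produces
ground-truthed cell tables and rendered images, so every downstream stage is
testable without any external data.

## The intensity code

The 8-bit scale is partitioned into **five levels of 51 intensity points**
(0–50, 51–101, 102–152, 153–203, 204–255); a cell's level in channel $k$ is
$\ell_k = \lfloor I_k / 51 \rfloor$ and its code is the tuple
$(\ell_1,\dots,\ell_K)$, $K \le 4$ channels. Numerical choices:

* $5 \times 51 = 255$ covers gray values 0–254; the single leftover value 255
  is clamped into the top level so the quantizer is total.
* The all-zero code is reserved for "unlabeled" (no fluorophore, no lineage
  mark); such cells are excluded from clone grouping and statistics.
* The simulator emits intensities at the **bin centers** $51\ell + 25$
  (25, 76, 127, 178, 229), which maximize the margin (25–26 gray values) to
  the quantizer boundaries. Whether a real labeling's five levels include a
  zero/background level is an open interpretation; the floor rule used here
  is one consistent reading, and the bin-center expression model is a
  stand-in for the unknown copy-number/intensity distribution of integrated
  cassettes — not a claim about it.

With intensity noise of standard deviation $\sigma$ around a bin center, a
channel decodes correctly with probability
$\Phi(26/\sigma) - \Phi(-25/\sigma)$ for interior levels (slightly more for
the clipped edge levels), and a $K$-channel code is exact only if all $K$
channels are. At $\sigma = 10$ this gives $\approx 0.991$ per channel but
only $\approx 0.991^4 \approx 0.966$ per 4-channel code — mild per-channel
noise is amplified by the code length. The test suite asserts the
per-cell accuracy bound at $\sigma = 8$, where the expected exact-code rate
($\approx 0.996$) clears 99% with margin; the monotone decay of accuracy
with noise is asserted separately over a seed-matched noise ladder.

## Multi-level thresholding and PSNR selection

`select_thresholds()` implements an iterative histogram-subdivision rule: a
worklist of intensity intervals starts with the occupied range; intervals
are processed in decreasing order of pixel mass; for the current interval
the occupancy-weighted mean $\mu$ and SD $\sigma$ are computed and
thresholds are emitted at $\mu - w\sigma$ and $\mu + w\sigma$ (at $\mu$
alone when $w = 0$; default $w = 1$), clipped inside the interval; recursion
continues on the **outer** sub-intervals. This member of the
histogram-iterative family was chosen for full determinism. Details that
make it well behaved:

* a threshold colliding with an existing one shifts by +1 intensity unit,
  preserving strict ordering;
* if the worklist empties before `n` thresholds exist (the outer-only
  recursion can strand mass in a middle segment), the current segments are
  re-scanned largest-mass-first, so `n` thresholds are always produced
  whenever the image has at least `n + 1` distinct values;
* a constant image is degenerate and is reported as a single-segment result
  (`n = 0`) rather than an arbitrary threshold.

Reconstruction replaces each pixel by its **segment mean** (not the interval
midpoint): segment means minimize RMSE for fixed thresholds, which makes
threshold refinement provably non-increasing in RMSE — a property the tests
assert on random images. PSNR is $20\log_{10}(255/\mathrm{RMSE})$, with an
exact reconstruction represented by the sentinel `Inf`, which orders above
every finite value.

`choose_optimal_n()` walks `n_range` (default 2–15) and returns the smallest
`n` whose PSNR gain over `n - 1` falls below `epsilon_db` (default 0.5 dB).
An elbow rule was preferred over "maximum PSNR" because segment-mean PSNR
increases monotonically with `n` and would always select the range maximum;
the saturating `n` is returned directly when reconstruction becomes exact.
On rendered synthetic fixtures the chosen `n` typically lands mid-range;
values in the high single digits are what one sees on real confocal
material, which is noisier than the simulator.

`detect_cells()` takes foreground as the union over channels of pixels at or
above each channel's lowest non-zero threshold (the procedure separates
fluorescent somata from background; no watershed splitting of touching cells
is attempted), labels 8-connected components, drops those below `min_area`
(default 5 px), and reports the unweighted 0-based pixel centroid scaled by
the pixel size.

**Core intensity measurement.** A cell's per-channel intensity is averaged
over the bright *core* of its component — pixels whose channel-summed
intensity reaches `core_frac` (default 0.95) of the component's peak —
rather than the full support. Edge roll-off pixels dilute a full-support
mean by a factor that depends on where the detection threshold happened to
fall; against *absolute* 51-point bins such a bias is fatal, while the core
mean estimates the soma's expression plateau directly. Setting
`core_frac = 0` recovers the plain support mean.

## The synthetic generator

`simulate_clones()` emulates the labeling whose readout the statistics
expect. Conventions: coordinates in micrometres, origin at the pial surface,
depth (`y_um`) increasing toward the white matter, half-open layer intervals
$[a, b)$. The default geometry is a ~1 mm six-layer slab (L1 0–100, L2/3
100–350, L4 350–500, L5 500–700, L6 700–950, SP 950–1000 µm; round-number
approximations of an early-postnatal mouse S1 column), 2000 µm wide, planar
by default with optional section thickness in z (serial sections of
100–150 µm are typical for cleared-tissue stacks).

* **Codes.** Each clone draws one non-zero code, by default without
  replacement (624 codes at 4 channels × 5 levels); with
  `unique_codes = FALSE` codes are drawn independently and clones can
  collide on a code at the birthday rate $\binom{k}{2}/624$, which the tests
  verify — real labelings have no uniqueness guarantee.
* **Clone sizes** come from three size classes, 1–8 / 9–16 / 17–32 cells,
  with probabilities 0.20 / 0.36 / 0.44 (uniform within a class): clones
  larger than 8 cells about twice as frequent as smaller ones, and the
  largest class most frequent, as in labelings that catch both early and
  late rounds of amplifying divisions.
* **Placement.** The anchor cell is uniform in the slab; every further
  member is displaced from the anchor at an exact distance drawn from a
  truncated normal — same-layer mates (probability $1 - 0.45$) with the
  vertical component confined to the anchor's layer, cross-layer mates
  (probability 0.45, roughly balancing the two related-pair categories)
  with the vertical component required to land in a different layer. The
  defaults are separations of 36.8 ± 20.5 µm (same layer) and
  142.1 ± 76.8 µm (cross layer). Two calibrations keep the *expected*
  realized separation equal to the requested mean despite the constraints:
  the truncated normal's location parameter is solved (by `uniroot` on the
  truncated mean) so its mean equals the target, and anchors for clones
  with cross-layer mates are drawn such that another layer is within reach
  of the smallest drawn cross distance, instead of re-drawing distances
  (which would bias them upward).
* **Hard core.** No two centroids come closer than `min_separation_um`
  (default 15 µm, about one soma diameter), and separation draws are
  truncated below at the same bound; when a clone packs its anchor ring
  full, the separation is re-drawn rather than violating the hard core.
  Somata therefore never fuse in the rendering, which is what makes exact
  count recovery a fair test of the detector rather than of a watershed.
* **Intensities** are bin centers plus $N(0, \sigma^2)$ noise, clipped to
  [0, 255], drawn in a single block after all placement so that the same
  seed yields the same underlying noise across `noise_sd` settings (this is
  what makes the accuracy-vs-noise monotonicity property exactly testable).
* **Unlabeled filler cells** can be added per layer to match a labeled
  fraction map (`laminar_fractions_s1()` provides a 40.2/31.3/19.8/29.0/
  27.2% preset); they carry level-0 intensities and decode to the reserved
  all-zero code.

`simulate_pair_distances()` generates at the pair level instead: distances
for the four (relatedness × layer-class) categories drawn directly from
calibrated truncated normals, with defaults 36.8 ± 20.5 / 142.1 ± 76.8 µm
(related, same/different layer) and 41.8 ± 17.3 / 294.9 ± 105.4 µm
(unrelated). This is the right granularity for validating
`summarize_dispersion()` itself, since a dispersion study's categories are
properties of pairs, not of a particular placement law.

**What the generator does not emulate:** point-spread-function anisotropy,
photobleaching, autofluorescence, partial-volume mixing of touching somata,
chromatic shifts, or the stoichiometry of electroporated constructs. Passing
tests demonstrate the correctness of the computations under the stated
generative model, not the robustness of segmentation on degraded real
images.

## Rendering

`render_image()` draws each cell, in every channel, as a uniformly filled
disk (radius 3 µm by default) with a Gaussian edge roll-off
(`pnorm((R - r)/sigma)`, σ = 0.8 px), scaled by the cell's nominal channel
intensity; contributions add, a constant background (default 8, below the
lowest non-zero bin center) is added, and the image is rounded and clipped
to 8 bits. A flat-top soma profile was chosen over a pure Gaussian bump
deliberately: the decoder reads *mean* intensities against absolute bins,
and a Gaussian profile scales every channel's measured mean by a
support-dependent factor near 0.5, which would make the code undecodable by
construction; filled somata with soft edges are also closer to how confocal
sections of cytoplasmic fluorophores actually look.

## Statistics

* **Pair table.** Related pairs are all within-clone pairs; unrelated pairs
  default to *all* cross-clone pairs within the same section (the
  `"matched"` policy subsamples them to the related count — how a study
  samples its unrelated pairs is genuinely underdetermined, so both are
  exposed). Pairs are classed same/different layer; distances are Euclidean
  over all supplied coordinate dimensions. Clones, and hence pairs, never
  span sections unless the user merges sections beforehand.
* **Mann–Whitney.** For pooled sizes ≤ 12 the U distribution is enumerated
  over all $\binom{n_a+n_b}{n_a}$ label assignments with midrank tie
  handling, and the two-sided p is twice the smaller tail, capped at 1;
  larger problems use the normal approximation with tie-corrected variance
  and continuity correction. The exact path is cross-checked in the tests
  against an independently coded brute-force enumeration and against
  `wilcox.test` on tie-free data; U is computed from rank sums, so
  million-pair tables cost no more than a sort.
* **Sidak**: $p_{\mathrm{adj}} = 1 - (1 - p)^m$, clipped to [0, 1].
* **Layer-count comparison**: per-layer Welch two-sample t-tests (unequal
  variances — replicate counts come from a handful of brains of unknown
  variance homogeneity), Sidak-adjusted across layers; effect size reported
  as $(\bar{x}_2 - \bar{x}_1)/\bar{x}_1$.
* **Laminar contribution**: labeled/total per layer plus count-weighted
  aggregates over supragranular (L2/3, L4), infragranular (L5, L6, SP) and
  all layers.
* **Excitatory fraction**: a lineage's share $f$ of *all* cortical cells is
  converted to its share of excitatory neurons as
  $f / (p_{\mathrm{neuron}} (1 - p_{\mathrm{interneuron}}))$, e.g.
  $0.30 / (0.64 \times 0.75) = 0.30/0.48 = 62.5\%$. When the labeled share
  is expressed against glutamatergic cells directly, slightly different
  figures (e.g. 67.5%) arise; this function implements the all-cells
  arithmetic and warns if the result exceeds 1.
* Two-sided tests everywhere by default.

## Problem sizes and determinism

Simulation-backed tests run at desk scale chosen once for statistical
adequacy: round-trip fixtures of 50 clones (~900 cells, a 2000 × 1000 µm
slab at 1 µm/px), noise-accuracy checks over ≥ 1000 cells, dispersion
recovery at 200–400 pairs per category (3-SE bands), enumeration
cross-checks up to 8 per group, and 100–150 replicate draws for rate
properties. Every stochastic step is seeded; `run_pipeline()` derives one
substream per stage from the master seed, and identical configuration plus
seed reproduces byte-identical outputs (the manifest records MD5 checksums
to make this checkable).

## Known limitations

* Code collisions between true clones are indistinguishable from clonal
  identity by construction; `group_clones(max_link_distance_um = ...)`
  offers single-linkage splitting as a sensitivity analysis, not a
  resolution of the ambiguity.
* Touching somata are merged (no watershed), so crowded real tissue will
  undercount; the generator's hard core sidesteps this by design.
* The elbow criterion and the subdivision weight $w$ are conventions; other
  members of the iterative-thresholding family will place thresholds
  differently while passing the same invariants.
* Cross-section clone continuity is not modeled: a clone spanning physical
  sections is counted once per section.
* The 4-channel exact-code accuracy at noise σ = 10 is ~96.6% for the
  reasons given above; pipelines requiring ≥ 99% exact codes need either
  σ ≤ 8 noise, fewer channels, or a code-aware (e.g. nearest-neighbor
  within observed codes) decoder, which is out of scope here.
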