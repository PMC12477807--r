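---
title: "Detecting and quantifying fluorescent puncta with punctate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and quantifying fluorescent puncta with punctate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(punctate)
```

## The problem

Single-molecule RNA-FISH and related fluorescence techniques render target
molecules as diffraction-limited 3D puncta over a noisy background. Counting
those puncta per cell is the basic quantitative readout, and the fragile step
is not finding local maxima — it is choosing the intensity threshold that
separates real spots from noise maxima. Plotting the number of retained
maxima against the threshold yields a curve whose elbow or plateau marks the
noise/signal boundary, but the curve's shape varies enormously between
high-expression, low-expression and variable-intensity images. punctate
implements a detection and automatic threshold-selection pipeline designed to
handle all three shapes without manual tuning, together with spot-level
quantification, benchmarking metrics, and a synthetic-image simulator that
closes the loop: every stage can be validated against generated ground truth.

## Detection model

Each z-slice of the stack is band-pass filtered with a Laplacian-of-Gaussian
(LoG): a normalized Gaussian blur of radius 7 px and width parameter
`amount = 2` (kernel side `2r + 1 = 15`), followed by a 3x3 edge-detection
kernel (-1 everywhere, +8 at the center, summing to zero). A border of width
7 px is zeroed on every slice, and negative responses are floored at zero so
integer intensity thresholds remain meaningful. Spot calls are 3D local
maxima of the filtered stack: voxels at or above the scan minimum that are
greater than or equal to all 26 neighbors (8 for 2D images) and strictly
above their slice's mean filtered intensity. Plateaus of equal-valued
adjacent maxima collapse to one call at the rounded component centroid, so
saturated spots produce exactly one call.

Two preprocessing guards run first: dead camera pixels (non-border positions
whose edge-filter response is at least the filtered slice mean plus 3 SD in
at least half of `max(6, ceiling(D/4))` evenly sampled slices) are replaced
by their 8-neighbor in-plane mean, and images with an intensity span below
256 are linearly rescaled to 0-511.

### Numerical choices

Convolution uses edge-replicate padding inside the LoG filter. We initially
used zero padding on the assumption that the subsequent border trim makes the
choice irrelevant, but it does not: the edge kernel sees the Gaussian's
padding roll-off one pixel *inside* the trim, so a constant image would
produce a spurious nonzero response ring at row/column `r + 1`. Replicate
padding restores the identity "constant image maps to exactly zero". The
generic convolution primitive (used by tests and the simulator) retains zero
padding and is verified against a naive nested-loop oracle to 1e-6.

The per-slice means used by the maxima filter are computed once on the
filtered, pre-threshold image (trimmed zeros included) and held fixed across
the threshold sweep. This makes the fast sweep — counting base maxima with
intensity at or above each threshold — exactly equivalent to re-running
maxima detection after zeroing sub-threshold voxels, a property the test
suite verifies exhaustively on small stacks.

## Threshold scan range

The scan minimum defaults to 10 a.u., dropping to 5 (or 1) when the 80th
percentile of the filtered image falls below 10 (or 5). The maximum is
500 a.u. unless both data-driven candidates — `ceiling(1.1 * q)` with `q`
the 99.9th percentile, and `floor(max / 10)` — exceed it, in which case the
smaller candidate is used. The 10% leeway on the percentile candidate is
exposed as a parameter.

## Automatic threshold selection

The selector operates on transforms of the spot-count curve:

1. **Difference curve.** The absolute first-difference of the counts;
   thresholds below the peak difference are trimmed so the curve begins at
   its highest point.
2. **Fano-factor window scores.** For window widths 5, 10, 15 and 20
   thresholds, each position is scored with the Fano factor
   (population variance / mean) of the difference curve in a centered
   window, shrunk at the curve ends; zero-mean windows score zero. The Fano
   transform normalizes local topology to the magnitude of counts so that
   candidate placement is comparable between images with hundreds and
   hundreds of thousands of maxima.
3. **MAD candidates.** On `y = log10(score + 1)`, for each factor `k` in
   -1 to 1 by 0.25, the lowest threshold with `y <= median(y) + k * MAD(y)`
   (unscaled MAD) is a candidate. When the MAD degenerates to zero, negative
   factors emit nothing. The `+ 1` inside the log handles exact zeros; since
   a global rescaling of counts shifts `y` by a constant, the candidates are
   scale-invariant (tested).
4. **Two-piece fit candidates.** Two independent least-squares lines are fit
   to the log-projected score curve, with the breakpoint chosen by
   exhaustive search over interior positions (at least 3 points per piece)
   minimizing total squared residuals. The breakpoint threshold and the
   leftmost threshold where the right-hand line meets or crosses the
   log10 projection of the original count curve both join the pool. Fitting
   on the raw rather than log curve is available via `fit_log = FALSE`.

The pooled candidates (all window sizes, both strategies) are combined as
`selected = round(wmean + lambda * sd)`, with equal candidate weights by
default (per-source weights are configurable) and `lambda` in
{-1, -0.5, 0, 0.5, 1} for presets `recall-strong` through
`precision-strong`. Because `mean + sd` can exceed the pool maximum for very
small pools, the selection is clamped to the pool range, preserving the
invariant pool-min <= selected <= pool-max. An empty pool raises an
"auto thresholding failed" error rather than guessing.

### Degenerate inputs

A flat count curve (zero difference everywhere) is un-thresholdable and
errors out. A strictly noiseless image is a subtler failure mode: its count
curve has no noise arm, so the peak-trim starts inside the signal drop and
the elbow heuristics have no boundary to find. Such images are exactly what
the zero-voxel-proportion (ZVP) quality metric flags: the fraction of
exactly-zero voxels in the filtered stack, with images at or above 0.7
flagged as artificially clean and excluded from benchmark summaries.

## Quantification

Each retained call is fitted slice-by-slice in a 9 x 9 x 5 crop with a 2D
Gaussian plus constant offset (Levenberg-Marquardt). The 3D parameters are
inferred from the per-slice fits: center and width from the slice with the
largest amplitude, z center as the amplitude-weighted mean slice, and z
extent as the FWHM of the per-slice amplitude profile. This 2D-to-3D scheme
is a deliberate design choice — fitting anisotropic 3D Gaussians directly is
costlier and less robust in crops this small. The local background is the
median of the crop's in-plane perimeter voxels, a robust estimate that a
centered spot cannot contaminate much. Total signal integrates
`max(I - background, 0)` over the ellipsoid with xy semi-axes
`2 sqrt(2 ln 2) sigma_xy` (the FWHM) and z semi-axis `z_extent / 2`, at
least one plane. Non-convergent fits fall back to the raw maximum with a
default PSF width of 1.5 px and are flagged.

Per-cell counts assign calls to cell labels by voxel lookup; calls on label
0 are reported separately so that counts are conserved. A cell is "ON" when
its count reaches the channel cutoff, inclusively — the defaults of 8 (for
an abundantly expressed target) and 2 (for a sparse one) transcripts per
cell follow common practice for stress-response mRNA counting in yeast.

Background masks derive from a transmitted-light stack: the per-pixel SD
over z is near-flat in background and variable inside cells. If the
projection's kernel-density estimate is genuinely bimodal (two dominant
modes separated by a valley dipping below half the smaller mode), the valley
is the threshold; otherwise the contrast-stretched histogram's right flank
is followed past its steepest descent until the derivative magnitude falls
below that minimum divided by `C = 2` (configurable). Holes under 64 px
enclosed by background are filled.

## Benchmarking

Calls match references greedily: candidate pairs within a Euclidean xy
distance of 4 voxels and 2 z planes (both inclusive) are accepted
closest-first, one-to-one. The greedy matcher agrees with an exhaustive
optimal assignment on small random point sets (tested). Precision, recall
and F-score follow the standard definitions with F = 0 when both are zero.
PR-AUC integrates precision over recall across the full threshold sweep,
extrapolating the polygon to both axes: horizontally from the lowest-recall
point to the precision axis, and from the highest-recall point to the corner
(recall 1, precision 0) — the convention under which a single perfect point
scores 1 and a single point at recall 0.5, precision 1 scores 0.75. For
simulated images a 7 px xy border is trimmed from calls and references
before matching, mirroring the simulator's spot-placement margin.

## The simulator

`simulate_stack()` emulates a single-channel FISH acquisition: a flat
background (default 500 a.u.) with Gaussian read noise (SD 50 a.u.), plus
anisotropic 3D Gaussian puncta (PSF sigma 1.3 px in xy, 0.9 planes in z —
typical of a 100x/1.4NA setup with ~65 nm pixels and 200-300 nm z steps) at
uniform subpixel positions inside a 7 px xy margin, with uniform relative
amplitude jitter and an optional clustered population. Output is quantized
to integers and fully determined by the seed.

Three degradations emulate real-image imperfections: a 3D Gaussian blur
(radius 7 xy / 2 z, amount 4) for diffuse GFP-like signal; edge darkening by
a factor drawn from U(0.01, 0.10) scaled with distance from the plane
center, with up to 5% noise on the filter; and defocus, blending each plane
with its radius-5 blurred version with weight growing linearly from 0 at the
center plane to `min(1, s_max - 1)` at the extremes, `s_max ~ U(1.1, 2.5)`.
The "strength-as-blend-weight" reading of defocus is this package's own
concrete interpretation, isolated inside that one function.

What the simulator does *not* reproduce: Poisson shot noise and camera gain
(noise is Gaussian), spatially correlated background structure, autofluorescence,
and optical aberrations beyond isotropic blur. Tests passing on simulated
stacks therefore demonstrate algorithmic correctness and clean-data
performance, not robustness to every experimental artifact.

## The standard benchmark batch

`benchmark_simulated_batch()` generates 40 stacks of 512 x 512 x 16 voxels
(seeds 1-40), each with 50-300 spots and amplitudes uniform in 400-1000 a.u.
— 8-20x the background noise SD — runs detection and the full threshold
sweep, and scores each image against its ground truth (7 px trim, standard
matching rule). ZVP-flagged images are excluded from summaries. The batch
size of 40 images keeps a full run in the ten-minute range on one core while
the per-image PR-AUC and F-score distributions are already stable; the same
machinery accepts any seed set for larger runs. On this batch the median
per-image PR-AUC and the mean F-score at automatically selected thresholds
are the package's two headline performance numbers, recomputed from scratch
by `scripts/acceptance.R` and asserted in the test suite.

## Known limitations

- Threshold selection on variable-intensity images finds the middle of the
  elbow; whether the start, middle or end of the bend is "right" is
  ultimately a user judgment, which the precision/recall presets expose but
  do not remove.
- The greedy matcher is not a globally optimal assignment in adversarial
  geometries (it agrees with one on random sets).
- Strictly noiseless images defeat the elbow heuristics by design; use the
  ZVP flag to detect them.
- Cluster/"cloud" decomposition of unresolvable aggregates is out of scope;
  clustered spots are called as however many maxima survive the filter.
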