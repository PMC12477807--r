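# punctate

Automated detection, threshold selection and quantification of fluorescent
puncta in 2D images and 3D image stacks.

Single-molecule RNA-FISH and similar fluorescence assays show each target
molecule as a diffraction-limited punctum. Turning such stacks into per-cell
molecule counts requires (i) enhancing blob-like signal, (ii) extracting
candidate maxima, and — the historically manual, subjective step —
(iii) choosing the intensity threshold that separates real spots from noise.
punctate automates the whole chain for high-throughput batches and ships a
synthetic-image simulator with ground truth so every stage is testable.

## Method at a glance

- **Detection.** Per-slice Laplacian-of-Gaussian filtering (normalized
  Gaussian, radius 7 px, width `a = 2`, followed by a 3x3 edge kernel with
  +8 center), border trim, negative floor; 3D local maxima (26-neighbor,
  plateau-collapsed) above the per-slice mean filtered intensity. Dead-pixel
  repair and conditional 0-511 rescaling run first.
- **Spot count curve.** Retained maxima vs. threshold over an auto-suggested
  scan range (default 10-500 a.u., data-adaptive at both ends).
- **Automatic thresholding.** On the trimmed absolute difference curve,
  sliding-window Fano factor scores (`sigma^2 / mu`, windows 5/10/15/20) are
  scanned with two strategies: lowest threshold with
  `log10(score + 1) <= median + k * MAD` for `k = -1, -0.75, ..., 1`, and a
  two-piece linear fit contributing its breakpoint and the first
  intersection of the right-hand line with the count curve. The candidate
  pool is combined as `round(mean + lambda * sd)` with presets
  `recall-strong ... precision-strong` mapping `lambda = -1 ... +1`.
- **Quantification.** Per-slice 2D Gaussian fits in 9x9x5 crops, 3D
  parameters inferred from the per-slice amplitude profile,
  background-subtracted signal integrated over the FWHM ellipsoid; per-cell
  counts and ON-cell statistics from label masks.
- **Benchmarking.** Greedy one-to-one matching within 4 voxels xy / 2
  planes z; recall `R = TP/(TP+FN)`, precision `P = TP/(TP+FP)`, F-score
  `2RP/(R+P)`, PR-AUC over the full sweep, SNR (`mu_A / sigma_B`), spot
  density per 9x9x5 box, and a zero-voxel-proportion quality filter
  (flag at >= 0.7).
- **Simulation.** Gaussian puncta (PSF sigma 1.3 px xy / 0.9 planes z) over
  Gaussian-noise background, amplitude jitter, optional clustering, and
  three degradations: 3D blur, edge darkening, per-plane defocus.

## Worked example

```r
library(punctate)

# simulate a small stack with known ground truth
p   <- sim_params(dims = c(128L, 128L, 12L), n_spots = 40L, seed = 7L)
sim <- simulate_stack(p)

# detect, select a threshold, benchmark against the truth
det <- detect_spots(sim$stack)
det
#> <spot_detection> 1916 base maxima, scan 1..500, ZVP 0.632

thr <- select_threshold(det$curve)
thr
#> <threshold_result> selected 69 (preset default; pool n=28, 25..278, mean 68.5 +/- 87.1)

sw <- pr_sweep(det, sim$truth, dims = stack_dim(sim$stack), trim_margin = 7)
glance(sw)
#> # A tibble: 1 x 5
#>   pr_auc best_f best_f_threshold max_recall n_thresholds
#>    <dbl>  <dbl>            <int>      <dbl>        <int>
#> 1  0.975  0.987               29      0.975          500

sw$f_score[sw$threshold == thr$selected]
#> [1] 0.9873418
```

Reading the output: 1916 base maxima survive the LoG filter at the scan
minimum — mostly noise. The selector pools 28 candidate thresholds from the
Fano/MAD and two-piece-fit strategies and settles on 69 a.u. Sweeping all
thresholds against the simulated ground truth gives an area under the
precision-recall curve of 0.975, and the call set at the automatically
selected threshold has an F-score of 0.987 — 39 of the 40 planted spots
recovered with zero false positives.

Plotting: `autoplot(det$curve, threshold = thr)` shows the count curve with
the selection and candidate pool; `autoplot(sw)` draws the PR curve;
`tidy(thr)` / `glance(thr)` expose the candidate pool and pool statistics as
tibbles.

A thin command-line wrapper with subcommands `simulate`, `detect`,
`threshold`, `quantify`, `benchmark`, `mip` and `pipeline` is installed at
`inst/cli/punctate.R` (e.g.
`Rscript "$(Rscript -e 'cat(system.file("cli/punctate.R", package="punctate"))')" detect --input stack.tif --out run1`).

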