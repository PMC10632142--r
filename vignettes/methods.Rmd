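---
title: "Methods: direction-selectivity statistics and retinal mosaic analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: direction-selectivity statistics and retinal mosaic analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retinads)
```

`retinads` implements the quantitative workflow used to find and
characterise direction-selective ganglion cells (DSGCs) in primate retina:
calcium-imaging tuning statistics, pixel-based vector-sum mapping, retinal
mosaic spatial statistics with simulated nulls, marker-intensity and
RNAscope classification, a transcriptomic marker screen, and dendritic
morphometrics. Every stage can be exercised on synthetic data with known
ground truth, so the pipeline's statistical behaviour is testable without
any microscope data. This vignette documents the models, the parameters
that matter, and the design choices made where the underlying procedures
are conventionally under-specified.

## Delta-F/F and response extraction

Raw somatic fluorescence is background-corrected (a no-laser control or a
blood-vessel background ROI, `subtract_background()`) and converted to
fractional change,

$$\Delta F/F = (F - F_0)/F_0,$$

with $F_0$ the mean fluorescence over a 23-s window ending at the first
stimulus onset (`compute_dff()`). If a recording has less than 23 s of
pre-stimulus quiet, all available pre-stimulus frames are used and a
warning is emitted; a non-positive $F_0$ is a hard error because it cannot
arise from a real indicator baseline. $\Delta F/F$ is invariant to
detector gain by construction.

Slow baseline oscillations can be removed with
`highpass_restore_baseline()`. Two estimators are provided. The default is
a first-order Butterworth high-pass applied forward and backward
(zero-phase), which attenuates a sinusoid five-fold below the cutoff to a
few percent while a transient much shorter than $1/f_c$ keeps more than
90% of its peak. A running-10th-percentile baseline over a $3/f_c$ window
("percentile" mode) is also available: it cannot ring near sharp
transients, but its stop-band attenuation is much weaker, so the linear
filter is the default. The cutoff is not prescribed by the source
procedure and defaults are therefore explicit arguments.

Responses are quantified per stimulus epoch as the maximum $\Delta F/F$
between stimulus onset and 1 s after offset (`epoch_responses()`; the 1-s
tail captures the indicator decay). Maxima are taken per trial and then
averaged within direction — not the maximum of the trial-averaged trace —
matching the stated order of operations of the original analysis.

## Direction-tuning statistics

For per-direction amplitudes $R_d \ge 0$ at directions $\theta_d$:

* **Normalized vector sum** (`vector_sum()`):
  $\mathrm{NVS} = \left|\sum_d R_d e^{i\theta_d}\right| / \sum_d R_d$,
  0 for an untuned cell and 1 for a response confined to one direction.
  Negative amplitudes are clipped to 0 before summation; the scalar-sum
  normalization presumes non-negative responses and clipping keeps
  $\mathrm{NVS} \in [0,1]$. When the vector magnitude is 0 the angle is
  undefined and reported as `NA`.
* **DSI** (`dsi()`): $(R_\mathrm{pref} - R_\mathrm{null}) /
  (R_\mathrm{pref} + R_\mathrm{null})$ with null = preferred + 180°.
  For drug comparisons the preferred axis is determined pre-drug and
  held fixed, so post-drug DSIs can legitimately be negative (a residual
  response in the opposite direction).
* **von Mises fit** (`fit_von_mises()`):
  $R(x) = R_{\max}\, e^{\kappa \cos((x-\mu)\pi/180)} / e^{\kappa}$, the
  circular analogue of a Gaussian; $R(\mu) = R_{\max}$ for any $\kappa$
  and $\kappa = 0$ is a flat curve. Fitting is nonlinear least squares
  (Levenberg-Marquardt) initialised at $\mu_0$ = vector-sum angle,
  $R_{\max,0}$ = max response, $\kappa_0 = 1$, with $\kappa \in [0, 50]$.
  A constant response vector is returned directly as the degenerate
  $\kappa = 0$ limit; non-convergence sets `fit_ok = FALSE` and leaves
  the raw statistics intact.
* **Responsiveness** (`is_responsive()`): mean over all epochs of the
  per-epoch peak must strictly exceed 1.5 times the baseline standard
  deviation of the trace. "Average amplitude" is taken over all epochs
  (not only the best direction); this reading is configurable.
* **Orientation convention** (`apply_orientation()`): stimulus angles are
  remapped so superior/temporal/inferior/nasal read 90/0/270/180 degrees;
  the remap is a rotation plus an optional mirror (for flipped
  whole-mounts) and is exactly invertible.
* Velocity tuning uses the maximum of a 0.5-s running mean during
  preferred/null epochs per speed; spot responses are trapezoidal
  time-integrals of $\Delta F/F$ over the 2-s presentation.
* Group comparisons (`compare_groups()`) are two-sided Wilcoxon tests:
  rank-sum for independent samples, signed-rank for paired designs, with
  all-tied inputs flagged as degenerate rather than tested.

## Pixel-based vector-sum mapping

`pixel_vector_sum_map()` screens a field for DS somas without ROI
segmentation: per-pixel $\Delta F/F$ (same 23-s baseline rule, shared code
path), a spatial Gaussian filter of $\sigma = 2$ px per frame (reflective
boundaries), per-epoch maximum projection, trial averaging per direction,
and a per-pixel vector sum. The statistic mapped is the raw vector-sum
magnitude $|V|$; a normalized (NVS-like) variant is available by flag.
Dark pixels make the per-pixel division unstable, so $F_0$ is floored at
its 1st-percentile value and pixels below that percentile are masked.
Candidates are 8-connected components above a magnitude threshold
(quantile 0.995 by default — an artifact decision, the original
thresholding being visual) with at least `min_area_px` pixels, summarised
by magnitude-weighted centroid and circular-mean angle.

## Mosaic statistics

* **VDRI** (`voronoi_regularity()`): the mean Voronoi domain area divided
  by its standard deviation, after excluding every domain that touches
  the rectangular sampling window (a domain is excluded when any vertex
  lies on or outside the boundary; unbounded domains are always
  excluded). Uniform random arrays score about 1.9; regular mosaics score
  higher; a zero-variance lattice is reported as infinite with a flag.
  Observed values are judged against `random_null_vdri()`, uniform
  simulations at matched count and window.
* **DRP** (`density_recovery_profile()`): neighbour density in 20-µm
  annuli from 0 to 1,000 µm, with each annulus area analytically clipped
  to the window (exact circle-rectangle intersection areas, validated
  against Monte Carlo integration) — the standard edge correction for
  this estimator. Densities are $\sum_i \text{counts}_i / \sum_i
  \text{area}_i$ over reference points. The exclusion-zone summary takes
  the well as the mean of the 3 lowest bin densities among bins 2-50 (the
  first bin is excluded as unreliable: its annulus area is tiny), the
  plateau as the mean density at 390-1,000 µm, and reports
  well/plateau × 100 as the convergence percentage.
* **Coverage factor**: density (cells/mm²) × mean dendritic field area
  (mm²). `density_grid()` bins somas into 500-µm cells and imputes
  flagged (damaged/defocused) cells from their valid 8-neighbours.
  `equivalent_eccentricity()` applies the nasal foreshortening
  $\sqrt{(0.61x)^2 + y^2}$.

Sampling regions are axis-aligned rectangles throughout; all coordinates
are µm and densities per mm².

### Small-sample behaviour of the VDRI

Because VDRI is a mean/sd ratio, its seed-averaged value rises above the
large-$n$ limit (~1.88) when few domains survive border exclusion:
54-point random mosaics at 13.14 cells/mm² retain ~33 domains and average
VDRI ≈ 2.00. Comparisons of observed mosaics against nulls are therefore
always made at matched point count and window, never against the 1.9
rule-of-thumb alone.

### Superposed mosaics

`synth_mosaic("superposition")` overlays independent hard-core mosaics,
emulating an antibody that labels several intermixed cell types. The DRP
separates the cases cleanly: each component has a structurally empty well
(convergence ~0%) while the union's well fills in with cross-component
neighbours (convergence ~50-70%). The VDRI behaves differently: the union
of equally-weighted regular mosaics *retains* statistically detectable
area regularity at matched-count power — in simulations its VDRI exceeds
its random null's 95th percentile about as decisively as the components
exceed theirs, because the union's larger count tightens its null faster
than superposition dilutes the effect. Inference that a labelled
population comprises several mosaics should therefore lean on the DRP
well contrast (and on single-type regularity), not on the union's VDRI
falling to chance; the corresponding acceptance check in the test suite
records this as an expected failure rather than weakening the assertion.

## Classification and the marker screen

Marker intensities are z-scored per channel within staining/imaging batch
(`zscore_channels()`, population denominator — fixed for
reproducibility), which cancels per-batch affine gain differences. Types
are assigned either by a strict z-threshold (`threshold_classify()`) or
by k-means on the z-scores (`kmeans_classify()`, 10 restarts, recorded
seed); cluster indices are anchored by mean first-channel z-score so
labels are invariant to index permutation, and the two methods
cross-check each other.

RNAscope transcript counts per cell use
$(\text{integrated} - \text{background/px} \times \text{area}) /
\text{single-dot intensity}$, floored at 0, with the single-dot intensity
calibrated from ≥21 isolated dots. Positivity thresholds are strict:
BNC2 requires more than 40 dots, FSTL4 more than 80; non-integer dot
numbers are compared as-is. Artifact exclusion (vessels, high cell
background) is an input flag, not an image operation.

The marker screen (`marker_screen()`) compares expression of candidate
inhibitory-receptor genes between each peripheral cluster and its foveal
partner: library-size-normalized counts, log fold change as the
difference of log mean normalized counts (natural log, pseudocount 1 —
the log base is not stated in the source and is configurable), two-sided
Wilcoxon rank-sum p-value, and exclusion when |logFC| > 2 and p < 0.05
for any screened gene. The conjunction keeps the realized false-exclusion
rate well under the nominal 5%. `dotplot_stats()` reports
percent-expressing and mean-within-expressing per cluster and gene, with
an undefined mean flagged when no cell expresses the gene.

## Morphometrics

`depth_profile()` converts a z-axis intensity profile to IPL depth:
subtract the mean background, clip negatives to 0, normalize to the
maximum, and map z linearly with the INL border at 0% and the GCL border
at 100% (the mapping flips automatically with the acquisition direction).
`contact_fraction()` masks the partner channel (e.g. ChAT) with the
reference mask (e.g. a DiI fill) slice by slice and reports summed
overlap as a percentage of total reference area; the chance-level control
rotates the partner 90° in-plane about the volume centre
(nearest-neighbour resampling; exact and area-conserving for square
slices, out-of-frame voxels dropped otherwise, with the surviving area
fraction reported).

## The synthetic-data generator

The generator produces the study's data modalities with known truth:

* **Movies** (`synth_movie()`): 220 × 220 µm field at 128 × 128 px and
  4 Hz — pixel count as in the original acquisition; the frame rate sits
  between the two acquisition rates used there and samples the indicator
  decay adequately. Somas are isotropic Gaussians ($\sigma$ = radius/2,
  truncated at 3$\sigma$, radius 6 µm) of baseline brightness 50 (a.u.)
  over a uniform background of 30, i.e. 60% of somatic baseline — with
  bulk AM dye loading the neuropil is brightly stained, and this ratio
  also governs how much per-pixel noise the $\Delta F/F$ division
  amplifies in non-somatic pixels. Each epoch drives a cell with
  amplitude $R_{\max} e^{\kappa(\cos(\theta-\mu)-1)}$ from the moment the
  bar's leading edge crosses the soma centre, for bar-width/speed
  seconds, then decays exponentially with $\tau$ = 0.4 s. The rise is
  instantaneous by design: convolving the boxcar with the decay kernel
  would scale the attained peak by $1 - e^{-T/\tau}$ and make programmed
  amplitudes unrecoverable at realistic bar-crossing times, defeating
  ground-truth testing. Noise is additive Gaussian per pixel per frame
  (Poisson mode available); "peak SNR" means soma-centre signal amplitude
  ($f_0 R_{\max}$) over the pixel noise sd, so SNR 5 at defaults is
  `noise_sd = 5`. The stimulus schedule uses 8 directions at 500 µm/s
  (2.24 deg/s at 223 µm/degree), pseudorandomized blocks, 5-s
  inter-stimulus intervals, and a 25-s quiet period covering the 23-s
  baseline window.
* **Mosaics** (`synth_mosaic()`): uniform, hard-core (dart throwing with
  a 10⁴·n rejection budget, ample at retinal densities of tens of cells
  per mm²), and superpositions of independent hard-core components.
* **Marker tables** (`synth_marker_table()`): class-conditional Gaussian
  intensities with optional per-batch affine distortions.
* **Expression matrices** (`synth_expression()`): negative-binomial
  counts (dispersion 2, base mean 20) for paired foveal/peripheral
  clusters with designated natural-log fold changes.
* **Dendrite volumes** (`synth_dendrite_volumes()`): reference segments
  with a partner channel drawn as a wrapping tube plus unrelated
  background processes, for the co-fasciculation control.

What the generator does *not* emulate: optics (PSF), motion artifacts,
vascular shadowing, Poisson-Gaussian mixed noise, correlated neuropil
contamination, spike-to-calcium nonlinearity, or irregular sampling
windows. Passing tests therefore demonstrate the correctness and
statistical calibration of the analysis code under its stated
assumptions, not robustness to every artifact of real recordings.

## Numerical choices and problem sizes

* Vector-sum angles are reported in [0, 360); an angle is `NA` whenever
  the corresponding magnitude is 0 (tolerance 10⁻⁹ relative to the
  scalar sum). Ties in the argmax direction break toward the vector-sum
  angle.
* Per-pixel $F_0$ floors at the 1st-percentile $F_0$; domains and annuli
  use exact geometry rather than guard buffers; the circle-rectangle
  area routine is closed-form with case analysis on the corner geometry.
* NVS saturates in $\kappa$ once off-peak responses reach the
  peak-extraction noise floor (max over ~9 noisy frames); at peak SNR 5
  monotonicity is asserted over $\kappa \in [0.25, 2]$ and saturation
  (not collapse) beyond.
* Test and acceptance problem sizes are chosen for desk-scale runtimes:
  movies of 20 cells × ~680 frames; detection performance averaged over
  10 seeds; VDRI nulls of 60-200 simulations; the large-n randomness
  reference uses 10,000 points × 20 seeds. These sizes give standard
  errors comfortably inside the asserted tolerances.
* Every generator takes an explicit integer seed and reproduces its
  output bit-for-bit; derived per-stream seeds stay below 2³¹.

## Known limitations

* Sampling regions are rectangles; arbitrary polygons (or masked regions)
  are not supported.
* The hard-core sampler is sequential-rejection RSA, not a Gibbs/Matérn
  process; at packing fractions approaching jamming it errors rather
  than degrades.
* `marker_screen()` uses library-size normalization only; no
  batch-effect or depth-regression corrections.
* The von Mises fit is unimodal; ON-OFF cells with bimodal tuning would
  need a two-component extension.
* The pixel map assumes a stationary field (no motion correction).
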