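# retinads

Direction-selectivity and mosaic analysis for retinal calcium imaging.

## What this is for

A rare retinal ganglion cell type — the ON-type direction-selective
ganglion cell (ON-DSGC) — can be found in primate retina by combining
two-photon calcium imaging of drifting-bar responses with molecular
markers and spatial statistics of soma mosaics. `retinads` implements that
quantitative workflow as reusable, tested R functions for anyone analysing
visual-response tuning and retinal cell-type anatomy:

* **Imaging**: ROI trace extraction, background subtraction,
  ΔF/F = (F − F₀)/F₀ with a 23-s pre-stimulus baseline, optional
  high-pass baseline restoration, and per-epoch peak response tables.
* **Tuning**: the normalized vector sum
  NVS = |Σ R_d e^{iθ_d}| / Σ R_d ∈ [0, 1], the direction-selectivity
  index DSI = (R_pref − R_null)/(R_pref + R_null), least-squares fits of
  the von Mises tuning curve R(x) = R_max e^{κ cos((x−μ)π/180)}/e^κ, a
  strict 1.5×-baseline-sd responsiveness criterion, retinal-orientation
  remapping, velocity and spot-size response metrics, and Wilcoxon
  group/paired comparisons.
* **DS mapping**: per-pixel vector-sum maps of a whole scan field
  (Gaussian-filtered ΔF/F movie → per-epoch max projections →
  per-direction means → per-pixel |V| and angle), with connected-component
  candidate detection — the screening step that locates DSGC somas before
  any ROI is drawn.
* **Mosaics**: Voronoi domain regularity index (VDRI = mean/sd of
  border-excluded domain areas; ~1.9 for random arrays), random-null
  simulations, Rodieck density recovery profiles with exact
  annulus-in-window edge correction and exclusion-zone convergence,
  coverage factors, 500-µm density grids with neighbour imputation, and
  the nasal equivalent-eccentricity transform √((0.61x)² + y²).
* **Classification**: per-batch z-scoring of marker intensities,
  threshold and k-means type assignment, RNAscope dot-count estimation
  ((integrated − background·area)/single-dot, thresholds >40/>80 dots),
  a fold-change + rank-sum marker screen for paired foveal/peripheral
  clusters, and dot-plot statistics.
* **Morphometrics**: IPL depth profiles (0% = INL border, 100% = GCL
  border) and DiI/ChAT co-fasciculation contact fractions with a
  90°-rotation chance control.
* **Synthetic data**: generators for drifting-bar calcium movies with von
  Mises-tuned somas, random / hard-core / superposed soma mosaics,
  bimodal marker tables, and paired-cluster expression matrices — all
  seed-deterministic with retained ground truth, so the whole pipeline is
  testable end to end.

## Worked example

```r
library(retinads)

# a synthetic field: 2 direction-selective somas among 6 untuned ones
sched  <- stim_schedule(n_trials = 3, seed = 1)
cells  <- synth_cells(n_ds = 2, n_other = 6, mu_deg = c(90, 225), kappa = 4, seed = 1)
bundle <- synth_movie(cells, sched, noise_sd = 5, seed = 1)

traces <- extract_traces(bundle$movie, truth_rois(cells, bundle$movie)) |>
  subtract_background(rep(bundle$background_f, dim(bundle$movie$stack)[1])) |>
  compute_dff(sched)

profiles <- tuning_profiles(epoch_responses(traces, sched),
                            traces = traces, schedule = sched)
profiles[, c("roi", "nvs", "pref_deg", "dsi", "mu_deg", "kappa", "responsive")]
#> # A tibble: 8 × 7
#>   roi       nvs pref_deg     dsi mu_deg   kappa responsive
#>   <chr>   <dbl>    <dbl>   <dbl>  <dbl>   <dbl> <lgl>
#> 1 1     0.578         90 0.860    89.3  3.13    TRUE
#> 2 2     0.556        225 0.812   225.   2.91    TRUE
#> 3 3     0.0178       315 0.0158    9.43 0.0351  TRUE
#> 4 4     0.00629      135 0.0201  192.   0.0126  TRUE
#> ...
```

The two implanted DS cells (preferred directions 90° and 225°) come out
with NVS ≈ 0.56–0.58, DSI ≈ 0.8–0.9 and fitted μ within a few degrees of
truth; the six untuned cells sit at NVS ≈ 0.01. The same field screened
without ROIs:

```r
vsmap <- pixel_vector_sum_map(bundle$movie, sched)
detect_candidates(vsmap)
#> # A tibble: 2 × 6
#>   candidate area_px centroid_x_um centroid_y_um angle_deg magnitude
#>       <int>   <int>         <dbl>         <dbl>     <dbl>     <dbl>
#> 1         1      42          66.6          86.0      86.0     0.249
#> 2         2      40         123.          185.      225.      0.238
```

Exactly the two DS somas are recovered, at their true positions and
preferred angles. A mosaic analysis with its simulated null:

```r
m  <- synth_mosaic("exclusion", density_per_mm2 = 30,
                   region = c(0, 2000, 0, 2000), d_min_um = 100, seed = 1)
vr <- voronoi_regularity(m)
glance(random_null_vdri(nrow(m), attr(m, "region"), n_sims = 100, seed = 2,
                        observed = attr(vr, "vdri")))
#> # A tibble: 1 × 8
#>   n_sims mean_vdri sd_vdri   q05   q95 observed quantile p_regular
#>    <int>     <dbl>   <dbl> <dbl> <dbl>    <dbl>    <dbl>     <dbl>
#> 1    100      1.90   0.202  1.64  2.27     3.80        1   0.00990
```

The hard-core mosaic's VDRI (3.80) sits above every random simulation
(null mean 1.90), i.e. the mosaic is significantly regular — the test
used to argue that labelled somas form a genuine single-type mosaic.

`autoplot()` methods cover the main result types (tuning curves on polar
axes, mirrored DRPs, VDRI null histograms, vector-sum maps, depth
profiles, mosaics), `tidy()`/`glance()` summarise fits, and
`run_pipeline()` executes a configured end-to-end run with a reproducible
manifest.

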