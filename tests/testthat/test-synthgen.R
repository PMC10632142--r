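test_that("stimulus schedules are time-ordered, non-overlapping, block-complete", {
  sched <- stim_schedule(n_trials = 3, seed = 7)
  expect_equal(nrow(sched), 24)
  expect_true(all(diff(sched$t_on_s) > 0))
  # non-overlap: every epoch ends before the next begins
  expect_true(all(head(sched$t_off_s, -1) < tail(sched$t_on_s, -1)))
  # within each block every direction appears exactly once
  per_block <- split(sched$direction_deg, sched$block)
  for (b in per_block) expect_setequal(b, seq(0, 315, by = 45))
  expect_true(all(sched$direction_deg %in% seq(0, 315, by = 45)))
  # inter-stimulus gap is respected
  gaps <- tail(sched$t_on_s, -1) - head(sched$t_off_s, -1)
  expect_true(all(abs(gaps - 5) < 1e-9))
})

test_that("schedule generation is seed-deterministic and supports speeds/spots", {
  expect_identical(stim_schedule(seed = 3), stim_schedule(seed = 3))
  multi <- stim_schedule(directions_deg = c(90, 270),
                         speed_um_s = c(125, 250, 500), n_trials = 2, seed = 1)
  expect_equal(nrow(multi), 12)
  per_block <- split(paste(multi$direction_deg, multi$speed_um_s), multi$block)
  expect_length(unique(per_block[[1]]), 6)
  spots <- stim_schedule(kind = "spot", spot_diam_um = c(25, 100, 400),
                         n_trials = 2, seed = 1)
  expect_equal(nrow(spots), 6)
  expect_true(all(abs(spots$t_off_s - spots$t_on_s - 2) < 1e-9))
  expect_error(stim_schedule(kind = "spot"), "spot_diam_um")
})

test_that("movie generation is bit-identical under a fixed seed", {
  cells <- synth_cells(n_ds = 1, n_other = 1, seed = 5)
  sched <- stim_schedule(n_trials = 1, seed = 5)
  a <- fast_movie(cells, sched, noise_sd = 2, seed = 11)
  b <- fast_movie(cells, sched, noise_sd = 2, seed = 11)
  expect_identical(a$movie$stack, b$movie$stack)
  c <- fast_movie(cells, sched, noise_sd = 2, seed = 12)
  expect_false(identical(a$movie$stack, c$movie$stack))
})

test_that("movie generator rejects impossible geometry and schedules", {
  sched <- stim_schedule(n_trials = 1, seed = 1)
  outside <- synth_cells(n_ds = 1, n_other = 0, seed = 1)
  outside$x_um <- 500
  expect_error(fast_movie(outside, sched), "inside the scan field")
})

test_that("an untuned cell responds identically in all directions", {
  cells <- synth_cells(n_ds = 0, n_other = 1, r_max = 0.5, seed = 2)
  sched <- stim_schedule(n_trials = 1, seed = 2)
  prof <- bundle_profiles(fast_movie(cells, sched))
  dm <- attr(prof, "direction_means")
  expect_lt(diff(range(dm$mean_peak_dff)) / max(dm$mean_peak_dff), 0.01)
  expect_lt(prof$nvs, 0.01)
})

test_that("a tuned cell yields positive NVS with argmax at its preferred direction", {
  cells <- synth_cells(n_ds = 1, n_other = 0, mu_deg = 90, kappa = 4, seed = 3)
  sched <- stim_schedule(n_trials = 1, seed = 3)
  prof <- bundle_profiles(fast_movie(cells, sched))
  expect_gt(prof$nvs, 0.5)
  expect_equal(prof$pref_deg, 90)
})

test_that("with r_max = 0 the extracted traces conserve baseline", {
  cells <- synth_cells(n_ds = 0, n_other = 3, r_max = 0, seed = 4)
  sched <- stim_schedule(n_trials = 1, seed = 4)
  b <- fast_movie(cells, sched, noise_sd = 2, seed = 9)
  tr <- extract_traces(b$movie, truth_rois(cells, b$movie))
  tr <- subtract_background(tr, rep(b$background_f, dim(b$movie$stack)[1]))
  tr <- compute_dff(tr, sched)
  for (id in unique(tr$roi)) {
    d <- tr$dff[tr$roi == id]
    expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(length(d)) + 1e-12)
  }
})

test_that("exclusion mosaics respect the hard-core distance", {
  m <- synth_mosaic("exclusion", density_per_mm2 = 30,
                    region = c(0, 2000, 0, 2000), d_min_um = 100, seed = 1)
  expect_gte(min(dist(cbind(m$x_um, m$y_um))), 100)
  expect_error(
    synth_mosaic("exclusion", density_per_mm2 = NA, n = 20,
                 region = c(0, 500, 0, 500), d_min_um = 200, seed = 1),
    "infeasible"
  )
})

test_that("random mosaics pass a 4x4 chi-square uniformity screen across seeds", {
  region <- c(0, 2000, 0, 2000)
  pass <- vapply(1:100, function(s) {
    m <- synth_mosaic("random", density_per_mm2 = NA, region = region,
                      n = 320, seed = s)
    gx <- cut(m$x_um, seq(0, 2000, length.out = 5), include.lowest = TRUE)
    gy <- cut(m$y_um, seq(0, 2000, length.out = 5), include.lowest = TRUE)
    counts <- as.vector(table(gx, gy))
    suppressWarnings(stats::chisq.test(counts)$p.value) > 0.01
  }, logical(1))
  expect_gte(mean(pass), 0.95)
})

test_that("superposed mosaics mix components at the requested total density", {
  m <- synth_mosaic("superposition", density_per_mm2 = 30,
                    region = c(0, 2000, 0, 2000), d_min_um = 150,
                    n_mosaics = 3, seed = 2)
  expect_setequal(unique(m$component), 1:3)
  expect_equal(nrow(m), 120)
  for (k in 1:3) {
    comp <- m[m$component == k, ]
    expect_gte(min(dist(cbind(comp$x_um, comp$y_um))), 150)
  }
  # cross-component pairs are unconstrained
  expect_lt(min(dist(cbind(m$x_um, m$y_um))), 150)
})

test_that("marker tables honour class fractions and reject bad inputs", {
  means <- matrix(c(10, 10, 10, 4), 2, 2,
                  dimnames = list(c("a", "b"), c("ch1", "ch2")))
  tbl <- synth_marker_table(2000, c(a = 0.3, b = 0.7), means, 1, seed = 1)
  expect_equal(nrow(tbl), 2000)
  frac_a <- mean(tbl$true_class == "a")
  expect_lt(abs(frac_a - 0.3), 3 * sqrt(0.3 * 0.7 / 2000))
  expect_error(synth_marker_table(10, c(a = 0.6, b = 0.6), means, 1), "sum to 1")
  expect_error(synth_marker_table(10, c(a = 0.5, b = 0.5), means, -1), "positive")
})

test_that("expression generator shifts designated genes and validates pairs", {
  pairs <- tibble::tibble(foveal = "fov1", peripheral = "per1")
  x <- synth_expression(n_genes = 10, cluster_pairs = pairs,
                        cells_per_cluster = 300,
                        log_fold = tibble::tibble(gene = "gene3",
                                                  peripheral = "per1",
                                                  log_fold = -3),
                        seed = 1)
  fov <- x$clusters$cell[x$clusters$cluster == "fov1"]
  per <- x$clusters$cell[x$clusters$cluster == "per1"]
  ratio <- mean(x$counts["gene3", per]) / mean(x$counts["gene3", fov])
  expect_lt(abs(log(ratio) - (-3)), 0.5)
  neutral <- mean(x$counts["gene1", per]) / mean(x$counts["gene1", fov])
  expect_lt(abs(log(neutral)), 0.3)
  expect_error(
    synth_expression(cluster_pairs = tibble::tibble(foveal = NA_character_,
                                                    peripheral = "p"),
                     seed = 1),
    "foveal partner"
  )
})
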