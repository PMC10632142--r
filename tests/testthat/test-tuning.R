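dirs8 <- seq(0, 315, by = 45)

test_that("vector sum matches a complex-arithmetic oracle on random cases", {
  set.seed(42)
  for (i in 1:25) {
    amps <- runif(8, 0, 3)
    vs <- vector_sum(amps, dirs8)
    z <- sum(amps * exp(1i * dirs8 * pi / 180))
    expect_equal(vs$magnitude, Mod(z), tolerance = 1e-12)
    expect_equal(vs$nvs, Mod(z) / sum(amps), tolerance = 1e-12)
    expect_equal(vs$angle_deg %% 360, (Arg(z) * 180 / pi) %% 360, tolerance = 1e-9)
    expect_true(vs$nvs >= 0 && vs$nvs <= 1)
  }
})

test_that("vector sum handles symmetric, single-direction and degenerate inputs", {
  expect_equal(vector_sum(rep(2, 8), dirs8)$nvs, 0, tolerance = 1e-12)
  one <- vector_sum(c(0, 0, 3, 0, 0, 0, 0, 0), dirs8)
  expect_equal(one$nvs, 1)
  expect_equal(one$angle_deg, 90)
  hand <- vector_sum(c(2, 1, 1, 1, 1, 1, 1, 1), dirs8)
  expect_equal(hand$nvs, 1 / 9, tolerance = 1e-12)
  expect_equal(hand$angle_deg, 0)
  zero <- vector_sum(rep(0, 8), dirs8)
  expect_equal(zero$nvs, 0)
  expect_true(is.na(zero$angle_deg))
  # negative amplitudes are clipped before summation, keeping nvs in [0, 1]
  clipped <- vector_sum(c(1, -5, 0, 0, 0, 0, 0, 0), dirs8)
  expect_equal(clipped$nvs, 1)
  expect_error(vector_sum(1:3, c(10, 10, 370)), "distinct")
})

test_that("nvs and dsi are invariant to multiplicative response scaling", {
  set.seed(1)
  amps <- runif(8)
  expect_equal(vector_sum(amps, dirs8)$nvs, vector_sum(5 * amps, dirs8)$nvs)
  expect_equal(dsi(0.8, 0.2), dsi(8, 2))
})

test_that("dsi follows its formula including the negative branch", {
  expect_equal(dsi(1, 1), 0)
  expect_equal(dsi(2, 0), 1)
  expect_equal(dsi(1, 3), -0.5)
  expect_true(is.na(dsi(0, 0)))
})

test_that("the von Mises model equals r_max at mu for any kappa", {
  for (k in c(0, 0.5, 2, 10, 50)) {
    expect_equal(von_mises(137, r_max = 2.5, mu_deg = 137, kappa = k), 2.5)
  }
  expect_equal(von_mises(dirs8, 1.2, 90, 0), rep(1.2, 8))
})

test_that("von Mises fits recover exact model parameters and the constant limit", {
  amps <- von_mises(dirs8, r_max = 1, mu_deg = 90, kappa = 2)
  fit <- fit_von_mises(dirs8, amps)
  expect_true(fit$fit_ok)
  expect_lt(abs(fit$r_max - 1) / 1, 0.01)
  expect_lt(ang_diff <- min(abs(fit$mu_deg - 90), 360 - abs(fit$mu_deg - 90)), 0.9)
  expect_lt(abs(fit$kappa - 2) / 2, 0.01)
  const <- fit_von_mises(dirs8, rep(0.7, 8))
  expect_equal(const$kappa, 0)
  expect_equal(const$r_max, 0.7)
  expect_error(fit_von_mises(c(0, 90, 180), c(1, 2, 1)), "4 directions")
  td <- tidy(fit)
  expect_equal(td$term, c("r_max", "mu_deg", "kappa"))
  expect_equal(nrow(glance(fit)), 1)
})

test_that("vector-sum angle agrees with fitted mu on noiseless model data", {
  for (k in c(0.5, 1, 2, 4, 8)) {
    amps <- von_mises(dirs8, 1, 225, k)
    vs <- vector_sum(amps, dirs8)
    fit <- fit_von_mises(dirs8, amps)
    d <- abs(vs$angle_deg - fit$mu_deg)
    expect_lt(min(d, 360 - d), 5)
  }
})

test_that("responsiveness uses a strict 1.5-sd criterion", {
  sched <- tiny_schedule(n_trials = 1)
  tt <- (0:199) / 4
  base <- rep(c(-0.01, 0.01), 50)
  make_trace <- function(amp) {
    dff <- c(base, numeric(100))
    for (i in seq_len(nrow(sched))) {
      dff[tt >= sched$t_on_s[i] & tt <= sched$t_off_s[i]] <- amp
    }
    dff
  }
  s <- sd(base)
  expect_false(is_responsive(make_trace(1.5 * s), tt, sched))   # exactly 1.5x
  expect_true(is_responsive(make_trace(10 * s), tt, sched))
  expect_false(is_responsive(c(base, numeric(100)), tt, sched)) # flat
})

test_that("orientation remapping is a bijection with the stated symmetries", {
  a <- c(0, 45, 90, 180, 270, 300)
  expect_equal(apply_orientation(a), a)
  flipped <- apply_orientation(c(0, 90, 180, 270), flip = TRUE)
  expect_equal(flipped, c(0, 270, 180, 90))
  round_trip <- apply_orientation(
    apply_orientation(a, rotate_deg = 37, flip = TRUE),
    rotate_deg = 37, flip = TRUE, invert = TRUE
  )
  expect_equal(round_trip, a)
})

test_that("velocity tuning recovers programmed speed profiles", {
  speeds <- c(125, 250, 500, 1000)
  sched <- stim_schedule(directions_deg = c(0, 180), speed_um_s = speeds,
                         n_trials = 2, seed = 8)
  gain <- c(`125` = 0.5, `250` = 1, `500` = 0.5, `1000` = 0.2)
  cells <- synth_cells(n_ds = 1, n_other = 0, mu_deg = 0, kappa = 3, seed = 8)
  cells$speed_gain <- list(gain)
  b <- fast_movie(cells, sched)
  tr <- extract_traces(b$movie, truth_rois(cells, b$movie)) |>
    subtract_background(rep(b$background_f, dim(b$movie$stack)[1])) |>
    compute_dff(sched)
  vt <- velocity_tuning(tr, sched, pref_deg = 0)
  pref <- vt[vt$axis == "pref", ]
  expect_equal(pref$speed_um_s[which.max(pref$peak_dff)], 250)
  # an untuned cell responds equally on both axes
  cells0 <- synth_cells(n_ds = 0, n_other = 1, seed = 9)
  b0 <- fast_movie(cells0, sched)
  tr0 <- extract_traces(b0$movie, truth_rois(cells0, b0$movie)) |>
    subtract_background(rep(b0$background_f, dim(b0$movie$stack)[1])) |>
    compute_dff(sched)
  vt0 <- velocity_tuning(tr0, sched, pref_deg = 0)
  wide <- tidyr::pivot_wider(vt0, names_from = "axis", values_from = "peak_dff")
  expect_equal(wide$pref, wide$null, tolerance = 0.05)
})

test_that("spot response integrals are trapezoidal time integrals", {
  sched <- stim_schedule(kind = "spot", spot_diam_um = 100, n_trials = 1,
                         t_first_s = 25, seed = 1)
  fs <- 10
  tt <- (0:699) / fs
  # constant 0.5 during the 2-s spot -> integral 1.0
  dff1 <- ifelse(tt >= sched$t_on_s & tt <= sched$t_off_s, 0.5, 0)
  tr1 <- compute_dff(traces_from_matrix(cbind(1 + dff1), frame_rate_hz = fs), sched)
  expect_equal(spot_response_integral(tr1, sched)$integral, 1, tolerance = 0.01)
  # triangular pulse peaking at 1 over the 2 s -> area 1.0
  mid <- (sched$t_on_s + sched$t_off_s) / 2
  tri <- pmax(0, 1 - abs(tt - mid))
  tr2 <- compute_dff(traces_from_matrix(cbind(1 + tri), frame_rate_hz = fs), sched)
  expect_equal(spot_response_integral(tr2, sched)$integral, 1, tolerance = 0.01)
  # zero trace -> 0
  tr3 <- compute_dff(traces_from_matrix(cbind(rep(1, 700)), frame_rate_hz = fs), sched)
  expect_equal(spot_response_integral(tr3, sched)$integral, 0)
})

test_that("group comparisons reproduce exact Wilcoxon behaviour", {
  expect_equal(compare_groups(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # completely separated n = 8 vs 8: exact two-sided p = 2 / choose(16, 8)
  sep <- compare_groups(1:8, 101:108)
  expect_equal(sep$p_value, 2 / choose(16, 8), tolerance = 1e-12)
  paired_same <- compare_groups(c(1, 2, 3), c(1, 2, 3), paired = TRUE)
  expect_equal(paired_same$p_value, 1)
  expect_true(paired_same$degenerate)
})

test_that("tuning recovery holds at peak SNR 5 and nvs increases with kappa", {
  # three cells per kappa in one noisy field; recovery judged per kappa
  # level. NVS rises with kappa until off-peak responses reach the
  # peak-extraction noise floor (~kappa 2 at this SNR), then saturates.
  kappas <- c(0.25, 0.5, 1, 2, 8)
  reps <- 3
  cells <- synth_cells(n_ds = length(kappas) * reps, n_other = 0,
                       mu_deg = 90, seed = 10)
  cells$kappa <- rep(kappas, each = reps)
  sched <- stim_schedule(n_trials = 3, seed = 10)
  b <- synth_movie(cells, sched, noise_sd = 5, seed = 10)
  prof <- bundle_profiles(b)
  prof <- prof[order(as.integer(prof$roi)), ]
  prof$kappa_true <- cells$kappa
  mu_err <- vapply(split(prof$mu_deg, prof$kappa_true), function(m) {
    d <- abs(m - 90)
    mean(pmin(d, 360 - d))
  }, numeric(1))
  expect_true(all(mu_err < 10))
  nvs_by_kappa <- tapply(prof$nvs, prof$kappa_true, mean)[as.character(kappas)]
  expect_gt(cor(nvs_by_kappa[1:4], kappas[1:4], method = "spearman"), 0.9)
  # saturation, not collapse, past the resolvable range
  expect_gt(nvs_by_kappa[["8"]], 0.8 * nvs_by_kappa[["2"]])
})
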