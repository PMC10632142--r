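#' Vector sum of per-direction responses
#'
#' Treats each direction's response amplitude as a vector of that length
#' pointing in the stimulus direction and sums them. The normalized vector
#' sum (NVS) divides the magnitude of this sum by the scalar sum of the
#' responses: 0 for a cell responding equally in all directions, 1 for a
#' cell responding in a single direction only. Negative amplitudes are
#' clipped to 0 before summation so the normalization holds.
#'
#' @param amplitudes Response amplitudes (e.g. trial-mean peak delta-F/F).
#' @param directions_deg Stimulus directions, degrees; at least 2 distinct.
#' @return A list with `magnitude`, `angle_deg` (`NA` when the magnitude is
#'   0, where the angle is undefined) and `nvs` (0 when all responses are
#'   0).
#' @examples
#' vector_sum(c(2, 1, 1, 1, 1, 1, 1, 1), seq(0, 315, by = 45))$nvs # 1/9
#' @export
vector_sum <- function(amplitudes, directions_deg) {
  if (length(unique(wrap_deg(directions_deg))) < 2) {
    abort("need responses in at least 2 distinct directions")
  }
  stopifnot(length(amplitudes) == length(directions_deg))
  r <- pmax(amplitudes, 0)
  th <- directions_deg * pi / 180
  vx <- sum(r * cos(th))
  vy <- sum(r * sin(th))
  mag <- sqrt(vx^2 + vy^2)
  scalar <- sum(r)
  tol <- 1e-9 * max(scalar, 1)
  list(
    magnitude = mag,
    angle_deg = if (mag > tol) wrap_deg(atan2(vy, vx) * 180 / pi) else NA_real_,
    nvs = if (scalar > 0) mag / scalar else 0
  )
}

#' Direction selectivity index
#'
#' `(pref - null) / (pref + null)`: 1 for a response confined to the
#' preferred direction, 0 for equal preferred and null responses, negative
#' when the response in the opposite (null) direction dominates — as seen
#' when GABAergic inhibition is blocked and the pre-drug preferred axis is
#' retained.
#'
#' @param pref,null Response amplitudes in the preferred and null
#'   (preferred + 180 degrees) directions.
#' @return DSI in `[-1, 1]`; `NA` when `pref + null` is 0 (undefined).
#' @export
dsi <- function(pref, null) {
  out <- (pref - null) / (pref + null)
  out[(pref + null) == 0] <- NA_real_
  out
}

#' von Mises tuning curve
#'
#' The circular analogue of a Gaussian used to model directional tuning:
#' `R(x) = r_max * exp(kappa * cos((x - mu) * pi / 180)) / exp(kappa)`, so
#' the curve equals `r_max` at the preferred direction `mu` for any `kappa`
#' and is constant (`r_max`) when `kappa = 0`.
#'
#' @param x_deg Direction(s), degrees.
#' @param r_max Peak response.
#' @param mu_deg Preferred direction, degrees.
#' @param kappa Tuning width parameter (>= 0; larger is narrower).
#' @return Model response at `x_deg`.
#' @export
von_mises <- function(x_deg, r_max, mu_deg, kappa) {
  r_max * exp(kappa * (cos((x_deg - mu_deg) * pi / 180) - 1))
}

#' Fit a von Mises tuning curve
#'
#' Least-squares fit of [von_mises()] to per-direction response amplitudes.
#' Initialised at the vector-sum angle (`mu`), the maximum response
#' (`r_max`) and `kappa = 1`, with `kappa` bounded to `[0, 50]`. A constant
#' response profile is the degenerate `kappa = 0` limit and is returned
#' directly. Non-convergence is reported via `fit_ok = FALSE` rather than
#' an error so the raw statistics survive.
#'
#' @param directions_deg Stimulus directions, degrees; at least 4.
#' @param amplitudes Response amplitudes (non-negative).
#' @return An object of class `vm_fit`: a list with `r_max`, `mu_deg`
#'   (in `[0, 360)`), `kappa`, `fit_ok`, `data` (a tibble of the input and
#'   fitted values), `rss`. Methods: [tidy.vm_fit()], [glance.vm_fit()],
#'   `predict`, `autoplot`.
#' @examples
#' amps <- von_mises(seq(0, 315, 45), r_max = 1, mu_deg = 90, kappa = 2)
#' fit <- fit_von_mises(seq(0, 315, 45), amps)
#' tidy(fit)
#' @export
fit_von_mises <- function(directions_deg, amplitudes) {
  if (length(directions_deg) < 4) abort("need at least 4 directions to fit")
  stopifnot(length(directions_deg) == length(amplitudes))
  x <- wrap_deg(directions_deg)
  y <- amplitudes
  vs <- vector_sum(y, x)
  make_fit <- function(r_max, mu_deg, kappa, fit_ok, note = NA_character_) {
    fitted <- von_mises(x, r_max, mu_deg, kappa)
    structure(
      list(r_max = r_max, mu_deg = if (is.na(mu_deg)) NA_real_ else wrap_deg(mu_deg),
           kappa = kappa, fit_ok = fit_ok, note = note,
           data = tibble::tibble(direction_deg = x, amplitude = y, fitted = fitted),
           rss = sum((y - fitted)^2)),
      class = "vm_fit"
    )
  }
  if (sd(y) == 0) {
    return(make_fit(mean(y), NA_real_, 0, TRUE, "constant response: kappa = 0 limit"))
  }
  mu0 <- vs$angle_deg %||% x[which.max(y)]
  if (is.na(mu0)) mu0 <- x[which.max(y)]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ von_mises(x, r_max, mu_deg, kappa),
      start = list(r_max = max(y), mu_deg = mu0, kappa = 1),
      lower = c(r_max = 0, mu_deg = mu0 - 360, kappa = 0),
      upper = c(r_max = Inf, mu_deg = mu0 + 360, kappa = 50),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(make_fit(max(y), mu0, 0, FALSE, conditionMessage(fit)))
  }
  p <- coef(fit)
  make_fit(unname(p["r_max"]), unname(p["mu_deg"]), unname(p["kappa"]), TRUE)
}

#' @export
print.vm_fit <- function(x, ...) {
  cat(sprintf("<vm_fit> r_max = %.4g, mu = %.1f deg, kappa = %.3g (%s)\n",
              x$r_max, x$mu_deg, x$kappa,
              if (x$fit_ok) "converged" else paste("failed:", x$note)))
  invisible(x)
}

#' Tidy a von Mises fit
#' @param x A `vm_fit`.
#' @param ... Unused.
#' @return Tibble with one row per parameter (`term`, `estimate`).
#' @export
tidy.vm_fit <- function(x, ...) {
  tibble::tibble(term = c("r_max", "mu_deg", "kappa"),
                 estimate = c(x$r_max, x$mu_deg, x$kappa))
}

#' One-row summary of a von Mises fit
#' @param x A `vm_fit`.
#' @param ... Unused.
#' @return Tibble with `r_max`, `mu_deg`, `kappa`, `rss`, `n`, `fit_ok`.
#' @export
glance.vm_fit <- function(x, ...) {
  tibble::tibble(r_max = x$r_max, mu_deg = x$mu_deg, kappa = x$kappa,
                 rss = x$rss, n = nrow(x$data), fit_ok = x$fit_ok)
}

#' @export
predict.vm_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$direction_deg else newdata
  von_mises(x, object$r_max, object$mu_deg %||% 0, object$kappa)
}

#' Responsiveness criterion for a trace
#'
#' A cell counts as responsive when its average stimulus response amplitude
#' strictly exceeds `threshold` (default 1.5) times the baseline standard
#' deviation of its delta-F/F trace. The amplitude is the mean over all
#' epochs of the per-epoch peak delta-F/F.
#'
#' @param dff Delta-F/F samples of one ROI.
#' @param time_s Sample times, seconds.
#' @param schedule A [stim_schedule()].
#' @param baseline_window_s Baseline window before the first onset, seconds.
#' @param threshold Multiple of the baseline sd that the mean amplitude must
#'   exceed (strictly).
#' @param tail_s Post-offset tail for the peak search, seconds.
#' @return Logical scalar.
#' @export
is_responsive <- function(dff, time_s, schedule, baseline_window_s = 23,
                          threshold = 1.5, tail_s = 1) {
  idx <- baseline_frames(time_s, min(schedule$t_on_s), baseline_window_s)
  if (length(idx) < 2) abort("baseline window contains fewer than 2 frames")
  base_sd <- sd(dff[idx])
  peaks <- purrr::map_dbl(seq_len(nrow(schedule)), function(i) {
    win <- time_s >= schedule$t_on_s[i] & time_s <= schedule$t_off_s[i] + tail_s
    max(dff[win])
  })
  mean(peaks) > threshold * base_sd
}

#' Map stimulus angles to retinal coordinates
#'
#' Preferred angles measured in stimulus (screen) coordinates are remapped
#' so that the retinal axes read superior = 90, temporal = 0, inferior =
#' 270 and nasal = 180 degrees. The remap is a rotation plus an optional
#' mirror about the horizontal axis (needed when the mounted retina is
#' flipped, which swaps superior and inferior); it is a bijection, and
#' applying it with `invert = TRUE` recovers the original angles.
#'
#' @param angles_deg Angles in degrees.
#' @param rotate_deg Rotation applied after the optional flip, degrees.
#' @param flip Mirror about the horizontal axis before rotating
#'   (90 becomes 270; 0 and 180 are fixed).
#' @param invert Apply the inverse mapping.
#' @return Remapped angles in `[0, 360)`.
#' @examples
#' apply_orientation(c(0, 90, 180, 270), flip = TRUE) # 0 270 180 90
#' @export
apply_orientation <- function(angles_deg, rotate_deg = 0, flip = FALSE,
                              invert = FALSE) {
  if (invert) {
    out <- angles_deg - rotate_deg
    if (flip) out <- -out
  } else {
    out <- if (flip) -angles_deg else angles_deg
    out <- out + rotate_deg
  }
  wrap_deg(out)
}

#' Velocity tuning from preferred/null bar responses
#'
#' For schedules probing several bar speeds, measures per speed the maximum
#' delta-F/F of the 0.5-s running-average response during preferred- and
#' null-direction epochs, averaged across trials.
#'
#' @param traces A `roi_traces` tibble with `dff` (see [compute_dff()]).
#' @param schedule A [stim_schedule()] with bar epochs at several speeds.
#' @param pref_deg Preferred direction of each ROI: either a single angle or
#'   a data frame `roi`, `pref_deg`. The null direction is `pref + 180`.
#' @param window_s Averaging window, seconds (default 0.5).
#' @param tail_s Post-offset tail, seconds.
#' @return Tibble `roi`, `speed_um_s`, `axis` (`"pref"`/`"null"`),
#'   `peak_dff` (trial mean).
#' @export
velocity_tuning <- function(traces, schedule, pref_deg, window_s = 0.5,
                            tail_s = 1) {
  if (is.null(traces[["dff"]])) abort("run compute_dff() first")
  fs <- attr(traces, "frame_rate_hz")
  k <- max(1L, round(window_s * fs))
  prefs <- if (is.data.frame(pref_deg)) pref_deg else
    tibble::tibble(roi = unique(traces$roi), pref_deg = pref_deg)
  bars <- schedule[schedule$kind == "bar", ]
  out <- purrr::map_dfr(split(seq_len(nrow(traces)), traces$roi), function(idx) {
    id <- traces$roi[idx[1]]
    pd <- prefs$pref_deg[match(id, prefs$roi)]
    tt <- traces$time_s[idx]
    sm <- as.numeric(stats::filter(traces$dff[idx], rep(1 / k, k), sides = 2))
    axis <- dplyr::case_when(
      ang_diff_deg(bars$direction_deg, pd) < 1e-6 ~ "pref",
      ang_diff_deg(bars$direction_deg, pd + 180) < 1e-6 ~ "null",
      TRUE ~ NA_character_
    )
    keep <- which(!is.na(axis))
    purrr::map_dfr(keep, function(i) {
      win <- tt >= bars$t_on_s[i] & tt <= bars$t_off_s[i] + tail_s
      tibble::tibble(roi = id, speed_um_s = bars$speed_um_s[i],
                     axis = axis[i], peak = max(sm[win], na.rm = TRUE))
    })
  })
  out |>
    dplyr::group_by(.data$roi, .data$speed_um_s, .data$axis) |>
    dplyr::summarise(peak_dff = mean(.data$peak), .groups = "drop")
}

#' Spot response integrals
#'
#' Time-integral (trapezoidal) of delta-F/F over each spot presentation,
#' per spot diameter, averaged across trials.
#'
#' @param traces A `roi_traces` tibble with `dff`.
#' @param schedule A [stim_schedule()] containing spot epochs.
#' @return Tibble `roi`, `spot_diam_um`, `integral` (delta-F/F x s).
#' @export
spot_response_integral <- function(traces, schedule) {
  if (is.null(traces[["dff"]])) abort("run compute_dff() first")
  spots <- schedule[schedule$kind == "spot", ]
  purrr::map_dfr(split(seq_len(nrow(traces)), traces$roi), function(idx) {
    id <- traces$roi[idx[1]]
    tt <- traces$time_s[idx]
    dd <- traces$dff[idx]
    purrr::map_dfr(seq_len(nrow(spots)), function(i) {
      win <- which(tt >= spots$t_on_s[i] & tt <= spots$t_off_s[i])
      integral <- if (length(win) < 2) 0 else
        sum(diff(tt[win]) * (head(dd[win], -1) + tail(dd[win], -1)) / 2)
      tibble::tibble(roi = id, spot_diam_um = spots$spot_diam_um[i],
                     integral = integral)
    })
  }) |>
    dplyr::group_by(.data$roi, .data$spot_diam_um) |>
    dplyr::summarise(integral = mean(.data$integral), .groups = "drop")
}

#' Nonparametric group comparisons
#'
#' Thin wrapper around the two-sided Wilcoxon tests used for population
#' comparisons of tuning statistics: rank-sum for independent groups (e.g.
#' NVS of one cell type versus others), signed-rank for paired designs
#' (e.g. DSI before versus during drug application).
#'
#' @param a,b Numeric samples. For `paired = TRUE`, matched by position.
#' @param paired Use the signed-rank test.
#' @return One-row tibble: `statistic`, `p_value`, `method`, `n_a`, `n_b`,
#'   `degenerate` (all observations tied, where the test is uninformative).
#' @export
compare_groups <- function(a, b, paired = FALSE) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  degenerate <- if (paired) all(a == b) else length(unique(c(a, b))) == 1
  if (degenerate) {
    return(tibble::tibble(
      statistic = NA_real_, p_value = 1,
      method = if (paired) "Wilcoxon signed rank" else "Wilcoxon rank sum",
      n_a = length(a), n_b = length(b), degenerate = TRUE
    ))
  }
  wt <- suppressWarnings(wilcox.test(a, b, paired = paired, exact = NULL))
  tibble::tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
                 method = wt$method, n_a = length(a), n_b = length(b),
                 degenerate = FALSE)
}

#' Per-ROI tuning profiles
#'
#' The central summary table: for each ROI, per-direction trial-mean
#' responses are reduced to the normalized vector sum, preferred direction,
#' DSI (null = preferred + 180 degrees; ties in the argmax direction are
#' broken toward the vector-sum angle), and a von Mises fit. When `traces`
#' are supplied the responsiveness criterion is evaluated too.
#'
#' @param responses An [epoch_responses()] table (single bar speed).
#' @param traces Optional `roi_traces` with `dff` for the responsiveness
#'   test.
#' @param schedule Required with `traces`.
#' @param pref_deg Optional data frame `roi`, `pref_deg` fixing each ROI's
#'   preferred axis (used to hold the pre-drug axis fixed when scoring
#'   post-drug responses); defaults to the argmax direction.
#' @param baseline_window_s,threshold Responsiveness parameters.
#' @return Tibble of class `tuning_profile`, one row per ROI: `roi`,
#'   `n_directions`, `nvs`, `vs_angle_deg`, `pref_deg`, `null_deg`, `dsi`,
#'   `r_max`, `mu_deg`, `kappa`, `fit_ok`, `responsive`, and a `vm_fit`
#'   list-column. Per-direction means are kept in the `direction_means`
#'   attribute.
#' @export
tuning_profiles <- function(responses, traces = NULL, schedule = NULL,
                            pref_deg = NULL, baseline_window_s = 23,
                            threshold = 1.5) {
  dm <- direction_means(responses)
  out <- dm |>
    dplyr::group_by(.data$roi) |>
    dplyr::group_modify(function(df, key) {
      amps <- df$mean_peak_dff
      dirs <- df$direction_deg
      vs <- vector_sum(amps, dirs)
      fixed <- if (!is.null(pref_deg)) pref_deg$pref_deg[match(key$roi, pref_deg$roi)]
      pref <- if (!is.null(fixed) && length(fixed) == 1 && !is.na(fixed)) {
        fixed
      } else {
        top <- which(amps == max(amps))
        if (length(top) > 1 && !is.na(vs$angle_deg)) {
          top <- top[which.min(ang_diff_deg(dirs[top], vs$angle_deg))]
        } else {
          top <- top[1]
        }
        dirs[top]
      }
      null_dir <- wrap_deg(pref + 180)
      amp_at <- function(d) {
        i <- which(ang_diff_deg(dirs, d) < 1e-6)
        if (length(i)) amps[i[1]] else NA_real_
      }
      fit <- fit_von_mises(dirs, amps)
      tibble::tibble(
        n_directions = length(dirs),
        nvs = vs$nvs,
        vs_angle_deg = vs$angle_deg,
        pref_deg = pref,
        null_deg = null_dir,
        dsi = dsi(amp_at(pref), amp_at(null_dir)),
        r_max = fit$r_max, mu_deg = fit$mu_deg, kappa = fit$kappa,
        fit_ok = fit$fit_ok,
        vm_fit = list(fit)
      )
    }) |>
    dplyr::ungroup()
  if (!is.null(traces)) {
    if (is.null(schedule)) abort("`schedule` is required with `traces`")
    resp <- purrr::map_dfr(split(seq_len(nrow(traces)), traces$roi), function(idx) {
      tibble::tibble(
        roi = traces$roi[idx[1]],
        responsive = is_responsive(traces$dff[idx], traces$time_s[idx],
                                   schedule, baseline_window_s, threshold)
      )
    })
    out <- dplyr::left_join(out, resp, by = "roi")
  } else {
    out$responsive <- NA
  }
  attr(out, "direction_means") <- dm
  class(out) <- c("tuning_profile", class(out))
  out
}
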