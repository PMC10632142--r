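#' Extract ROI fluorescence traces from a movie
#'
#' Averages the movie over each ROI mask, frame by frame, producing a tidy
#' trace table.
#'
#' @param movie A [ca_movie()].
#' @param rois Named list of logical Y x X masks (e.g. from [truth_rois()]).
#' @return A tibble of class `roi_traces`, long format: `roi`, `time_s`,
#'   `f`. Frame rate and ROI masks are kept as attributes.
#' @export
extract_traces <- function(movie, rois) {
  d <- dim(movie$stack)
  if (is.null(names(rois))) names(rois) <- as.character(seq_along(rois))
  flat <- matrix(movie$stack, d[1], d[2] * d[3])
  times <- frame_times(movie)
  out <- purrr::imap_dfr(rois, function(mask, id) {
    if (!is.logical(mask) || !all(dim(mask) == d[2:3])) {
      abort(sprintf("ROI '%s' is not a logical mask matching the movie", id))
    }
    if (!any(mask)) abort(sprintf("ROI '%s' is empty", id))
    tibble::tibble(roi = id, time_s = times,
                   f = rowMeans(flat[, as.vector(mask), drop = FALSE]))
  })
  new_roi_traces(out, frame_rate_hz = movie$frame_rate_hz)
}

new_roi_traces <- function(x, frame_rate_hz) {
  attr(x, "frame_rate_hz") <- frame_rate_hz
  if (!inherits(x, "roi_traces")) class(x) <- c("roi_traces", class(x))
  x
}

#' Subtract a background trace from every ROI
#'
#' Removes stimulus bleed-through and ambient signal, estimated either from
#' a no-laser control recording or from a background ROI drawn over an
#' indicator-free structure such as a blood vessel.
#'
#' @param traces A `roi_traces` tibble (see [extract_traces()]).
#' @param background Numeric vector with one value per frame, or a
#'   data frame with columns `time_s` and `f` on the same time base.
#' @return The traces with `f` replaced by `f - background`.
#' @export
subtract_background <- function(traces, background) {
  if (is.data.frame(background)) background <- background$f
  n_frames <- length(unique(traces$time_s))
  if (length(background) == 1) background <- rep(background, n_frames)
  if (length(background) != n_frames) {
    abort(sprintf("background has %d samples but traces have %d frames",
                  length(background), n_frames))
  }
  out <- traces |>
    dplyr::group_by(.data$roi) |>
    dplyr::mutate(f = .data$f - background) |>
    dplyr::ungroup()
  new_roi_traces(out, attr(traces, "frame_rate_hz"))
}

# frames belonging to the baseline window: the LAST `window_s` seconds
# before the first stimulus onset (all available pre-stimulus frames, with a
# warning, if the recording starts later than that)
baseline_frames <- function(time_s, t_first_on, window_s = 23) {
  pre <- which(time_s < t_first_on)
  if (length(pre) == 0) abort("no pre-stimulus frames for the baseline window")
  want <- time_s >= t_first_on - window_s & time_s < t_first_on
  if (min(time_s) > t_first_on - window_s) {
    warn(sprintf("only %.1f s of pre-stimulus recording available for the %g-s baseline window",
                 t_first_on - min(time_s), window_s))
  }
  which(want)
}

#' Compute delta-F/F traces
#'
#' For each ROI, `dff = (F - F0) / F0`, where `F0` is the mean fluorescence
#' over a window (default 23 s) ending at the first stimulus onset. If less
#' pre-stimulus recording is available, all of it is used with a warning.
#'
#' @param traces A `roi_traces` tibble.
#' @param schedule A [stim_schedule()]; its first `t_on_s` anchors the
#'   baseline window (alternatively give `t_stim_on`).
#' @param baseline_window_s Baseline window length, seconds.
#' @param t_stim_on First stimulus onset, seconds; overrides `schedule`.
#' @return The traces with a `dff` column added; per-ROI `F0` values are in
#'   the `f0` attribute (a tibble `roi`, `f0`).
#' @export
compute_dff <- function(traces, schedule = NULL, baseline_window_s = 23,
                        t_stim_on = NULL) {
  t_first <- t_stim_on %||% min(schedule$t_on_s)
  if (is.null(t_first)) abort("supply `schedule` or `t_stim_on`")
  out <- traces |>
    dplyr::group_by(.data$roi) |>
    dplyr::group_modify(function(df, key) {
      idx <- baseline_frames(df$time_s, t_first, baseline_window_s)
      f0 <- mean(df$f[idx])
      if (!is.finite(f0) || f0 <= 0) {
        abort(sprintf("non-physical baseline F0 = %g for ROI '%s'", f0, key$roi))
      }
      df$dff <- (df$f - f0) / f0
      df$f0 <- f0
      df
    }) |>
    dplyr::ungroup()
  f0 <- dplyr::distinct(out, .data$roi, .data$f0)
  out$f0 <- NULL
  out <- new_roi_traces(out, attr(traces, "frame_rate_hz"))
  attr(out, "f0") <- f0
  attr(out, "t_stim_on") <- t_first
  attr(out, "baseline_window_s") <- baseline_window_s
  out
}

#' High-pass filter traces to restore a drifting baseline
#'
#' Removes slow baseline oscillations while preserving stimulus-locked
#' transients. Two estimators are available: `"butterworth"` applies a
#' zero-phase (forward-backward) first-order Butterworth high-pass at
#' `cutoff_hz`; `"percentile"` subtracts a running 10th-percentile baseline
#' computed over a window of `3 / cutoff_hz` seconds, which cannot ring but
#' attenuates slow components less sharply.
#'
#' @param traces A `roi_traces` tibble.
#' @param cutoff_hz High-pass cutoff, Hz; must be below the Nyquist rate.
#' @param method `"butterworth"` or `"percentile"`.
#' @param column Which column to filter (`"f"` or `"dff"`).
#' @return The traces with the chosen column replaced by its filtered
#'   version.
#' @export
highpass_restore_baseline <- function(traces, cutoff_hz,
                                      method = c("butterworth", "percentile"),
                                      column = "f") {
  method <- match.arg(method)
  fs <- attr(traces, "frame_rate_hz")
  if (is.null(fs)) {
    ts <- sort(unique(traces$time_s))
    fs <- 1 / median(diff(ts))
  }
  if (cutoff_hz >= fs / 2) {
    abort(sprintf("cutoff %.3g Hz is not below the Nyquist rate %.3g Hz",
                  cutoff_hz, fs / 2))
  }
  filt <- function(x) {
    if (method == "butterworth") {
      bw <- signal::butter(1, cutoff_hz / (fs / 2), type = "high")
      as.numeric(signal::filtfilt(bw, x))
    } else {
      x - running_quantile(x, width = max(3L, round(3 / cutoff_hz * fs)), p = 0.1)
    }
  }
  out <- traces |>
    dplyr::group_by(.data$roi) |>
    dplyr::mutate(dplyr::across(dplyr::all_of(column), filt)) |>
    dplyr::ungroup()
  new_roi_traces(out, fs)
}

# centred running quantile with truncated windows at the edges
running_quantile <- function(x, width, p) {
  n <- length(x)
  half <- width %/% 2
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - half)
    hi <- min(n, i + half)
    unname(quantile(x[lo:hi], p, names = FALSE))
  }, numeric(1))
}

#' Per-epoch peak responses
#'
#' For every ROI and stimulus epoch, the peak delta-F/F within the epoch
#' window extended by `tail_s` seconds (to capture the indicator decay).
#' Peaks are taken per trial; direction averages ([direction_means()])
#' average these per-trial maxima.
#'
#' @param traces A `roi_traces` tibble with a `dff` column
#'   (see [compute_dff()]).
#' @param schedule A [stim_schedule()] whose epochs all lie inside the
#'   recording.
#' @param tail_s Post-offset tail included in the peak search, seconds.
#' @return A tibble with one row per ROI x epoch: `roi`, `epoch`, `block`,
#'   `kind`, `direction_deg`, `speed_um_s`, `spot_diam_um`, `peak_dff`.
#' @export
epoch_responses <- function(traces, schedule, tail_s = 1) {
  if (is.null(traces[["dff"]])) abort("run compute_dff() first")
  t_max <- max(traces$time_s)
  if (any(schedule$t_off_s > t_max)) {
    abort("schedule contains epochs outside the recording")
  }
  sched <- schedule |>
    dplyr::select("epoch", "block", "kind", "direction_deg", "speed_um_s",
                  "spot_diam_um", "t_on_s", "t_off_s") |>
    tibble::as_tibble()
  by_roi <- split(seq_len(nrow(traces)), traces$roi)
  purrr::imap_dfr(by_roi, function(idx, id) {
    tt <- traces$time_s[idx]
    dd <- traces$dff[idx]
    peaks <- purrr::map_dbl(seq_len(nrow(sched)), function(i) {
      win <- tt >= sched$t_on_s[i] & tt <= sched$t_off_s[i] + tail_s
      if (!any(win)) abort("no frames fall inside a stimulus epoch")
      max(dd[win])
    })
    dplyr::bind_cols(tibble::tibble(roi = id),
                     sched[, c("epoch", "block", "kind", "direction_deg",
                               "speed_um_s", "spot_diam_um")],
                     tibble::tibble(peak_dff = peaks))
  })
}

#' Trial-mean responses per direction
#'
#' @param responses An [epoch_responses()] table (bar epochs).
#' @return A tibble `roi`, `direction_deg`, `speed_um_s`, `n_trials`,
#'   `mean_peak_dff`.
#' @export
direction_means <- function(responses) {
  responses |>
    dplyr::filter(.data$kind == "bar") |>
    dplyr::group_by(.data$roi, .data$direction_deg, .data$speed_um_s) |>
    dplyr::summarise(n_trials = dplyr::n(),
                     mean_peak_dff = mean(.data$peak_dff),
                     .groups = "drop")
}
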