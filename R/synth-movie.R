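#' Build a drifting-bar / spot stimulus schedule
#'
#' Constructs the timetable of stimulus epochs used both by the movie
#' generator and by the response-extraction code. Bar conditions are the
#' cross of `directions_deg` and `speed_um_s`; spot conditions are the spot
#' diameters. Conditions are presented in pseudorandomized blocks: within
#' each block every condition appears exactly once (in a fresh random order)
#' before any repeats, with a fixed inter-stimulus gap.
#'
#' @param directions_deg Motion directions on the retina, degrees. The
#'   standard protocol uses the 8 directions `seq(0, 315, by = 45)`.
#' @param speed_um_s Bar speed(s) on the retina, µm/s.
#' @param n_trials Number of blocks (repeats per condition).
#' @param isi_s Inter-stimulus interval, seconds.
#' @param t_first_s Onset of the first epoch; everything before it is the
#'   quiet period used for baseline estimation, so it should be at least the
#'   baseline window (23 s) plus a margin.
#' @param sweep_um Distance travelled by the bar's leading edge during one
#'   epoch (it starts `sweep_um/2` before the field centre, along the motion
#'   axis); epoch duration is `sweep_um / speed`.
#' @param bar_width_um,bar_length_um Bar geometry, µm.
#' @param kind `"bar"` or `"spot"`.
#' @param spot_diam_um Spot diameters, µm (spot kind).
#' @param spot_dur_s Spot presentation time, seconds (default 2).
#' @param seed Seed for the block-order permutations.
#' @return A tibble of class `stim_schedule` with one row per epoch:
#'   `epoch`, `block`, `kind`, `direction_deg`, `speed_um_s`,
#'   `bar_width_um`, `bar_length_um`, `spot_diam_um`, `t_on_s`, `t_off_s`.
#' @examples
#' sched <- stim_schedule(n_trials = 3, seed = 1)
#' nrow(sched) # 24 epochs
#' @export
stim_schedule <- function(directions_deg = seq(0, 315, by = 45),
                          speed_um_s = 500,
                          n_trials = 3,
                          isi_s = 5,
                          t_first_s = 25,
                          sweep_um = 600,
                          bar_width_um = 300,
                          bar_length_um = 1000,
                          kind = c("bar", "spot"),
                          spot_diam_um = NULL,
                          spot_dur_s = 2,
                          seed = 1) {
  kind <- match.arg(kind)
  stopifnot(n_trials >= 1, isi_s >= 0, t_first_s >= 0)
  conditions <- if (kind == "bar") {
    tidyr::expand_grid(direction_deg = wrap_deg(directions_deg),
                       speed_um_s = speed_um_s) |>
      dplyr::mutate(kind = "bar",
                    bar_width_um = bar_width_um,
                    bar_length_um = bar_length_um,
                    spot_diam_um = NA_real_,
                    dur_s = sweep_um / .data$speed_um_s)
  } else {
    if (is.null(spot_diam_um)) abort("`spot_diam_um` required for spot schedules")
    tibble::tibble(direction_deg = NA_real_, speed_um_s = NA_real_,
                   kind = "spot", bar_width_um = NA_real_,
                   bar_length_um = NA_real_, spot_diam_um = spot_diam_um,
                   dur_s = spot_dur_s)
  }
  set.seed(seed)
  rows <- purrr::map_dfr(seq_len(n_trials), function(b) {
    conditions[sample.int(nrow(conditions)), ] |>
      dplyr::mutate(block = b)
  })
  dur <- rows$dur_s
  t_on <- t_first_s + cumsum(dplyr::lag(dur + isi_s, default = 0))
  out <- rows |>
    dplyr::mutate(epoch = dplyr::row_number(),
                  t_on_s = t_on,
                  t_off_s = t_on + dur) |>
    dplyr::select("epoch", "block", "kind", "direction_deg", "speed_um_s",
                  "bar_width_um", "bar_length_um", "spot_diam_um",
                  "t_on_s", "t_off_s")
  attr(out, "isi_s") <- isi_s
  attr(out, "sweep_um") <- sweep_um
  attr(out, "seed") <- seed
  class(out) <- c("stim_schedule", class(out))
  out
}

#' Ground-truth cells for synthetic movies
#'
#' Lays out direction-selective (von Mises tuned) and untuned somas in the
#' scan field, with a hard minimum separation so somas do not overlap.
#'
#' @param n_ds,n_other Numbers of direction-selective and untuned cells.
#' @param field_um Scan-field size `c(width, height)`, µm.
#' @param mu_deg Preferred directions of the DS cells; recycled. `NULL`
#'   draws them uniformly from the 8 cardinal/oblique directions.
#' @param kappa Tuning width of DS cells (untuned cells have kappa 0).
#' @param r_max Peak delta-F/F response amplitude.
#' @param radius_um Soma radius (Gaussian sigma is `radius_um / 2`).
#' @param baseline_f0 Resting fluorescence of each soma, arbitrary units.
#' @param tau_s Indicator decay time constant, seconds.
#' @param margin_um Keep-out border so somas stay inside the field.
#' @param seed Integer seed.
#' @return A tibble of class `truth_cells` with one row per cell:
#'   `cell_id`, `x_um`, `y_um`, `radius_um`, `baseline_f0`, `r_max`,
#'   `mu_deg`, `kappa`, `tau_s`, `class_label`.
#' @export
synth_cells <- function(n_ds = 5, n_other = 15,
                        field_um = c(220, 220),
                        mu_deg = NULL,
                        kappa = 4,
                        r_max = 0.5,
                        radius_um = 6,
                        baseline_f0 = 50,
                        tau_s = 0.4,
                        margin_um = 3 * radius_um,
                        seed = 1) {
  n <- n_ds + n_other
  stopifnot(n >= 1, kappa >= 0, r_max >= 0, baseline_f0 > 0)
  set.seed(seed)
  region <- c(margin_um, field_um[1] - margin_um, margin_um, field_um[2] - margin_um)
  xy <- hardcore_points(n, region, d_min_um = 4 * radius_um)
  mu <- if (is.null(mu_deg)) sample(seq(0, 315, by = 45), max(n_ds, 1), replace = TRUE)
        else wrap_deg(mu_deg)
  out <- tibble::tibble(
    cell_id = seq_len(n),
    x_um = xy[, 1],
    y_um = xy[, 2],
    radius_um = radius_um,
    baseline_f0 = baseline_f0,
    r_max = r_max,
    mu_deg = c(rep_len(mu, n_ds), runif(n_other, 0, 360)),
    kappa = c(rep(kappa, n_ds), rep(0, n_other)),
    tau_s = tau_s,
    class_label = c(rep("ds", n_ds), rep("other", n_other))
  )
  class(out) <- c("truth_cells", class(out))
  out
}

#' Generate a synthetic calcium-imaging movie
#'
#' Renders a T x Y x X fluorescence stack of somas responding to the drifting
#' bars (or spots) of a stimulus schedule. Each soma is an isotropic 2D
#' Gaussian (sigma = radius/2, truncated at 3 sigma) of resting brightness
#' `baseline_f0` on top of a uniform background level; its response to an
#' epoch with direction theta is a delta-F/F transient of amplitude
#' `r_max * exp(kappa * (cos(theta - mu) - 1))` that switches on when the
#' bar's leading edge crosses the soma centre, stays on while the bar covers
#' it (bar width / speed), and then decays exponentially with the indicator
#' time constant. Per-pixel Gaussian read noise of sd `noise_sd` is added.
#'
#' @param cells A [synth_cells()] table (cells outside the field are an
#'   error).
#' @param schedule A [stim_schedule()]; it must start no earlier than frame
#'   one and the quiet period before the first epoch is the baseline window.
#' @param field_um Scan-field size `c(width, height)`, µm.
#' @param px_per_um Pixels per µm (e.g. 64 px / 220 µm = 0.29).
#' @param frame_rate_hz Acquisition rate, Hz.
#' @param noise_sd Additive Gaussian noise sd per pixel per frame, in the
#'   same arbitrary units as `baseline_f0`.
#' @param noise One of `"gaussian"` (default) or `"poisson"`; the Poisson
#'   mode draws each pixel from a Poisson with the noiseless mean.
#' @param background_f Uniform background fluorescence (indicator-free
#'   signal reaching the detector); subtracting it is what
#'   [subtract_background()] emulates.
#' @param tail_s Extra recording time after the last epoch, seconds.
#' @param seed Integer seed; same seed reproduces the stack exactly.
#' @return A list of class `synth_movie_bundle`: `movie` (a `ca_movie`),
#'   `schedule`, `cells`, `background_f`, `noise_sd`, `seed`.
#' @export
synth_movie <- function(cells, schedule,
                        field_um = c(220, 220),
                        px_per_um = 128 / 220,
                        frame_rate_hz = 4,
                        noise_sd = 0,
                        noise = c("gaussian", "poisson"),
                        background_f = 30,
                        tail_s = 3,
                        seed = 1) {
  noise <- match.arg(noise)
  stopifnot(frame_rate_hz > 0, noise_sd >= 0, background_f >= 0)
  if (any(cells$x_um < 0 | cells$x_um > field_um[1] |
          cells$y_um < 0 | cells$y_um > field_um[2])) {
    abort("all cells must lie inside the scan field")
  }
  nx <- max(2L, round(field_um[1] * px_per_um))
  ny <- max(2L, round(field_um[2] * px_per_um))
  t_end <- max(schedule$t_off_s) + tail_s
  n_frames <- ceiling(t_end * frame_rate_hz)
  if (min(schedule$t_on_s) < 0) abort("schedule starts before the recording")
  times <- (seq_len(n_frames) - 1) / frame_rate_hz
  if (max(schedule$t_off_s) > max(times)) {
    abort("schedule is longer than the movie")
  }
  px_x <- (seq_len(nx) - 0.5) / px_per_um
  px_y <- (seq_len(ny) - 0.5) / px_per_um
  n_px <- nx * ny

  flat <- matrix(background_f, n_frames, n_px)
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    sig <- cell$radius_um / 2
    dx2 <- outer(px_y, px_x, function(y, x) (x - cell$x_um)^2 + (y - cell$y_um)^2)
    g <- exp(-dx2 / (2 * sig^2))
    g[dx2 > (3 * sig)^2] <- 0
    a <- cell_dff_course(cell, schedule, times, field_um = field_um)
    flat <- flat + (cell$baseline_f0 * (1 + a)) %o% as.vector(g)
  }
  set.seed(seed)
  if (noise == "gaussian") {
    if (noise_sd > 0) flat <- flat + rnorm(length(flat), sd = noise_sd)
  } else {
    flat <- matrix(stats::rpois(length(flat), pmax(flat, 0)), nrow(flat), ncol(flat))
  }
  stack <- array(flat, dim = c(n_frames, ny, nx))
  movie <- ca_movie(stack, frame_rate_hz = frame_rate_hz, px_per_um = px_per_um)
  structure(
    list(movie = movie, schedule = schedule, cells = cells,
         background_f = background_f, noise_sd = noise_sd, seed = seed),
    class = "synth_movie_bundle"
  )
}

# delta-F/F time course of one cell over the whole schedule; the bar path is
# centred on the scan field, so the soma's projection onto the motion axis
# (relative to the field centre) sets its response latency
cell_dff_course <- function(cell, schedule, times, field_um = c(220, 220)) {
  a <- numeric(length(times))
  sweep <- attr(schedule, "sweep_um") %||% 600
  for (i in seq_len(nrow(schedule))) {
    ep <- schedule[i, ]
    if (ep$kind == "bar") {
      th <- ep$direction_deg * pi / 180
      proj <- (cell$x_um - field_um[1] / 2) * cos(th) +
        (cell$y_um - field_um[2] / 2) * sin(th)
      t_hit <- ep$t_on_s + (proj + sweep / 2) / ep$speed_um_s
      dur <- ep$bar_width_um / ep$speed_um_s
      amp <- cell$r_max * exp(cell$kappa * (cos(th - cell$mu_deg * pi / 180) - 1))
    } else {
      t_hit <- ep$t_on_s
      dur <- ep$t_off_s - ep$t_on_s
      amp <- cell$r_max
    }
    if (!is.null(cell[["speed_gain"]]) && !is.na(ep$speed_um_s)) {
      amp <- amp * speed_gain_lookup(cell$speed_gain[[1]], ep$speed_um_s)
    }
    on <- times >= t_hit & times <= t_hit + dur
    decay <- times > t_hit + dur
    a[on] <- a[on] + amp
    a[decay] <- a[decay] + amp * exp(-(times[decay] - t_hit - dur) / cell$tau_s)
  }
  a
}

speed_gain_lookup <- function(gain, speed) {
  if (is.function(gain)) return(gain(speed))
  if (!is.null(names(gain))) {
    g <- gain[as.character(speed)]
    return(ifelse(is.na(g), 1, unname(g)))
  }
  1
}

#' Construct a calcium movie object
#'
#' @param stack Numeric array, frames x rows x columns (T x Y x X).
#' @param frame_rate_hz Acquisition rate, Hz.
#' @param px_per_um Pixels per µm.
#' @param t0_s Time of the first frame, seconds.
#' @return An object of class `ca_movie`.
#' @export
ca_movie <- function(stack, frame_rate_hz, px_per_um = 1, t0_s = 0) {
  stopifnot(length(dim(stack)) == 3, frame_rate_hz > 0)
  structure(
    list(stack = stack, frame_rate_hz = frame_rate_hz,
         px_per_um = px_per_um, t0_s = t0_s),
    class = "ca_movie"
  )
}

#' @export
print.ca_movie <- function(x, ...) {
  d <- dim(x$stack)
  cat(sprintf("<ca_movie> %d frames of %d x %d px at %.2f Hz (%.2f px/um)\n",
              d[1], d[2], d[3], x$frame_rate_hz, x$px_per_um))
  invisible(x)
}

#' @export
print.synth_movie_bundle <- function(x, ...) {
  cat("<synth_movie_bundle>\n")
  print(x$movie)
  cat(sprintf("  %d cells (%d DS), %d epochs, noise sd %.3g, seed %d\n",
              nrow(x$cells), sum(x$cells$kappa > 0), nrow(x$schedule),
              x$noise_sd, x$seed))
  invisible(x)
}

#' Frame times of a movie
#' @param movie A `ca_movie`.
#' @return Numeric vector of frame times, seconds.
#' @export
frame_times <- function(movie) {
  movie$t0_s + (seq_len(dim(movie$stack)[1]) - 1) / movie$frame_rate_hz
}

#' Circular ROI masks from ground-truth cells
#'
#' @param cells A [synth_cells()] table.
#' @param movie The `ca_movie` they were rendered into.
#' @param radius_scale Mask radius as a multiple of the soma radius.
#' @return Named list of logical Y x X masks, one per cell.
#' @export
truth_rois <- function(cells, movie, radius_scale = 1) {
  d <- dim(movie$stack)
  px_x <- (seq_len(d[3]) - 0.5) / movie$px_per_um
  px_y <- (seq_len(d[2]) - 0.5) / movie$px_per_um
  masks <- purrr::map(seq_len(nrow(cells)), function(i) {
    r <- cells$radius_um[i] * radius_scale
    outer(px_y, px_x, function(y, x)
      (x - cells$x_um[i])^2 + (y - cells$y_um[i])^2 <= r^2)
  })
  names(masks) <- as.character(cells$cell_id)
  masks
}

#' Write / read a movie as multi-page TIFF with a JSON sidecar
#'
#' The stack is scaled to [0, 1] for TIFF storage (32-bit float); the
#' sidecar records the scale factor, frame rate, pixel size and schedule so
#' the round trip is lossless up to float precision.
#'
#' @param bundle A `synth_movie_bundle` (or bare `ca_movie`).
#' @param path Output TIFF path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(bundle, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("the 'tiff' package is required to write TIFF movies")
  }
  movie <- if (inherits(bundle, "ca_movie")) bundle else bundle$movie
  stack <- movie$stack
  scale <- max(abs(stack), 1e-12)
  pages <- purrr::map(seq_len(dim(stack)[1]), function(t) stack[t, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(scale = scale, frame_rate_hz = movie$frame_rate_hz,
               px_per_um = movie$px_per_um, t0_s = movie$t0_s)
  if (inherits(bundle, "synth_movie_bundle")) {
    meta$schedule <- as.data.frame(bundle$schedule)
    meta$cells <- as.data.frame(bundle$cells)
    meta$seed <- bundle$seed
    meta$background_f <- bundle$background_f
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("the 'tiff' package is required to read TIFF movies")
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  stack <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (t in seq_along(pages)) stack[t, , ] <- pages[[t]] * meta$scale
  ca_movie(stack, frame_rate_hz = meta$frame_rate_hz,
           px_per_um = meta$px_per_um, t0_s = meta$t0_s %||% 0)
}
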