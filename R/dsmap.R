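#' Pixel-based vector-sum map
#'
#' Screens a scan field for direction-selective somas without segmenting
#' ROIs first. The movie is converted to per-pixel delta-F/F (per-pixel F0
#' from the same 23-s pre-stimulus rule as the trace pipeline), spatially
#' Gaussian-filtered (sigma = `sigma_px` pixels, reflective boundary),
#' max-projected within each bar epoch, and trial-averaged per direction;
#' each pixel's per-direction responses are then combined into a vector sum
#' whose magnitude highlights directional pixels and whose angle gives the
#' local preferred direction.
#'
#' Dark pixels make per-pixel delta-F/F unstable: F0 is floored at the
#' `f0_floor_quantile` quantile of the F0 image and pixels below that
#' quantile are masked out of the maps.
#'
#' @param movie A [ca_movie()].
#' @param schedule A [stim_schedule()] with at least 2 bar directions.
#' @param sigma_px Spatial Gaussian sigma, pixels.
#' @param baseline_window_s Pre-stimulus baseline window, seconds.
#' @param tail_s Post-offset tail included in the epoch projection, seconds.
#' @param normalized If `TRUE` the per-pixel magnitude is divided by the
#'   per-pixel scalar sum of (non-negative) responses, giving an NVS map;
#'   the default is the raw vector-sum magnitude.
#' @param f0_floor_quantile Quantile of the F0 image used as floor/mask.
#' @return An object of class `vs_map`: list with `magnitude` and
#'   `angle_deg` (Y x X matrices; angle `NA` where the magnitude is 0 or the
#'   pixel is masked), `per_direction` (named list of Y x X mean response
#'   images), `mask` (logical, usable pixels), `px_per_um`, `sigma_px`.
#' @export
pixel_vector_sum_map <- function(movie, schedule, sigma_px = 2,
                                 baseline_window_s = 23, tail_s = 1,
                                 normalized = FALSE,
                                 f0_floor_quantile = 0.01) {
  bars <- schedule[schedule$kind == "bar", ]
  dirs <- sort(unique(bars$direction_deg))
  if (length(dirs) < 2) abort("schedule must contain at least 2 bar directions")
  d <- dim(movie$stack)
  times <- frame_times(movie)
  base_idx <- baseline_frames(times, min(schedule$t_on_s), baseline_window_s)
  flat <- matrix(movie$stack, d[1], d[2] * d[3])
  f0 <- colMeans(flat[base_idx, , drop = FALSE])
  floor_val <- max(quantile(f0, f0_floor_quantile), .Machine$double.eps)
  mask <- matrix(f0 >= floor_val, d[2], d[3])
  dff <- sweep(flat, 2, pmax(f0, floor_val), "-")
  dff <- sweep(dff, 2, pmax(f0, floor_val), "/")

  kr <- gauss_conv_matrix(d[2], sigma_px)
  kc <- gauss_conv_matrix(d[3], sigma_px)
  # per-epoch maximum projection of the blurred delta-F/F movie
  epoch_imgs <- purrr::map(seq_len(nrow(bars)), function(i) {
    win <- which(times >= bars$t_on_s[i] & times <= bars$t_off_s[i] + tail_s)
    if (length(win) == 0) abort("a stimulus epoch contains no frames")
    proj <- matrix(-Inf, d[2], d[3])
    for (t in win) {
      fr <- kr %*% matrix(dff[t, ], d[2], d[3]) %*% kc
      proj <- pmax(proj, fr)
    }
    proj
  })
  per_dir <- purrr::map(dirs, function(th) {
    idx <- which(bars$direction_deg == th)
    Reduce(`+`, epoch_imgs[idx]) / length(idx)
  })
  names(per_dir) <- as.character(dirs)
  th <- dirs * pi / 180
  vx <- Reduce(`+`, purrr::map2(per_dir, cos(th), `*`))
  vy <- Reduce(`+`, purrr::map2(per_dir, sin(th), `*`))
  mag <- sqrt(vx^2 + vy^2)
  if (normalized) {
    scalar <- Reduce(`+`, purrr::map(per_dir, function(m) pmax(m, 0)))
    mag <- ifelse(scalar > 0, mag / scalar, 0)
  }
  ang <- wrap_deg(atan2(vy, vx) * 180 / pi)
  ang[mag <= 0] <- NA_real_
  mag[!mask] <- NA_real_
  ang[!mask] <- NA_real_
  structure(
    list(magnitude = mag, angle_deg = ang, per_direction = per_dir,
         mask = mask, px_per_um = movie$px_per_um, sigma_px = sigma_px),
    class = "vs_map"
  )
}

#' @export
print.vs_map <- function(x, ...) {
  cat(sprintf("<vs_map> %d x %d px, %d directions, peak |V| = %.3g\n",
              nrow(x$magnitude), ncol(x$magnitude), length(x$per_direction),
              max(x$magnitude, na.rm = TRUE)))
  invisible(x)
}

# dense convolution matrix for a 1D Gaussian with reflective boundary
gauss_conv_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- ceiling(3 * sigma)
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  m <- matrix(0, n, n)
  for (off in -r:r) {
    idx <- seq_len(n) + off
    idx <- ifelse(idx < 1, 2 - idx, ifelse(idx > n, 2 * n - idx, idx)) # reflect
    m[cbind(seq_len(n), idx)] <- m[cbind(seq_len(n), idx)] + k[off + r + 1]
  }
  m
}

#' Detect candidate DS somas in a vector-sum map
#'
#' Thresholds the magnitude map (by quantile of the usable pixels, or an
#' absolute value), labels 8-connected components, and keeps those with at
#' least `min_area_px` pixels. Each candidate is summarised by its
#' magnitude-weighted centroid and circular-mean angle.
#'
#' @param map A `vs_map`.
#' @param threshold Quantile in (0, 1] of the magnitude map (default
#'   0.995), or an absolute magnitude when `absolute = TRUE`.
#' @param min_area_px Minimum component area, pixels.
#' @param absolute Interpret `threshold` as an absolute magnitude.
#' @return Tibble with one row per candidate: `candidate`, `area_px`,
#'   `centroid_x_um`, `centroid_y_um`, `angle_deg`, `magnitude` (peak
#'   within the component), ordered by decreasing magnitude. Zero rows when
#'   nothing is above threshold.
#' @export
detect_candidates <- function(map, threshold = 0.995, min_area_px = 4,
                              absolute = FALSE) {
  mag <- map$magnitude
  if (!absolute && (threshold <= 0 || threshold > 1)) {
    abort("quantile threshold must be in (0, 1]")
  }
  thr <- if (absolute) threshold else
    quantile(mag[!is.na(mag)], threshold, names = FALSE)
  bw <- !is.na(mag) & mag >= thr & mag > 0
  labels <- label_components(bw)
  ids <- setdiff(unique(as.vector(labels)), 0L)
  if (length(ids) == 0) return(empty_candidates())
  px_per_um <- map$px_per_um
  out <- purrr::map_dfr(ids, function(id) {
    px <- which(labels == id, arr.ind = TRUE)
    if (nrow(px) < min_area_px) return(NULL)
    w <- mag[px]
    ang <- map$angle_deg[px] * pi / 180
    mean_ang <- wrap_deg(atan2(sum(w * sin(ang)), sum(w * cos(ang))) * 180 / pi)
    tibble::tibble(
      area_px = nrow(px),
      centroid_x_um = sum(w * (px[, 2] - 0.5)) / sum(w) / px_per_um,
      centroid_y_um = sum(w * (px[, 1] - 0.5)) / sum(w) / px_per_um,
      angle_deg = mean_ang,
      magnitude = max(w)
    )
  })
  if (nrow(out) == 0) return(empty_candidates())
  out |>
    dplyr::arrange(dplyr::desc(.data$magnitude)) |>
    dplyr::mutate(candidate = dplyr::row_number(), .before = 1)
}

empty_candidates <- function() {
  tibble::tibble(candidate = integer(), area_px = integer(),
                 centroid_x_um = numeric(), centroid_y_um = numeric(),
                 angle_deg = numeric(), magnitude = numeric())
}

# 8-connected component labelling (two-pass union-find)
label_components <- function(bw) {
  ny <- nrow(bw); nx <- ncol(bw)
  labels <- matrix(0L, ny, nx)
  parent <- integer(0)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  nxt <- 0L
  for (x in seq_len(nx)) {
    for (y in seq_len(ny)) {
      if (!bw[y, x]) next
      nbs <- integer(0)
      if (y > 1 && labels[y - 1, x] > 0) nbs <- c(nbs, labels[y - 1, x])
      if (x > 1) {
        if (labels[y, x - 1] > 0) nbs <- c(nbs, labels[y, x - 1])
        if (y > 1 && labels[y - 1, x - 1] > 0) nbs <- c(nbs, labels[y - 1, x - 1])
        if (y < ny && labels[y + 1, x - 1] > 0) nbs <- c(nbs, labels[y + 1, x - 1])
      }
      if (length(nbs) == 0) {
        nxt <- nxt + 1L
        parent[nxt] <- nxt
        labels[y, x] <- nxt
      } else {
        roots <- vapply(unique(nbs), find, integer(1))
        keep <- min(roots)
        labels[y, x] <- keep
        for (r in roots) parent[r] <- keep
      }
    }
  }
  if (nxt > 0) {
    for (i in seq_len(nxt)) parent[i] <- find(i)
    pos <- which(labels > 0)
    labels[pos] <- parent[labels[pos]]
    # compact label ids
    labels[pos] <- match(labels[pos], sort(unique(labels[pos])))
  }
  labels
}

#' Match detected candidates against ground truth
#'
#' Greedy nearest matching of candidates to true DS cells within
#' `match_radius_um`; used to score detection performance on synthetic
#' fields.
#'
#' @param candidates A [detect_candidates()] table.
#' @param cells A [synth_cells()] table; only rows with `kappa > 0` count
#'   as true DS cells.
#' @param match_radius_um Maximum centroid-to-soma distance for a match.
#' @return One-row tibble: `n_true`, `n_detected`, `tp`, `fp`, `fn`,
#'   `sensitivity`, `precision`, `mean_angle_err_deg` (over matched pairs,
#'   candidate angle vs true preferred direction).
#' @export
ds_detection_metrics <- function(candidates, cells, match_radius_um = 15) {
  truth <- cells[cells$kappa > 0, ]
  n_true <- nrow(truth)
  n_det <- nrow(candidates)
  used <- rep(FALSE, n_det)
  tp <- 0L
  ang_err <- numeric(0)
  for (i in seq_len(n_true)) {
    if (n_det == 0) break
    dists <- sqrt((candidates$centroid_x_um - truth$x_um[i])^2 +
                  (candidates$centroid_y_um - truth$y_um[i])^2)
    dists[used] <- Inf
    j <- which.min(dists)
    if (length(j) && dists[j] <= match_radius_um) {
      used[j] <- TRUE
      tp <- tp + 1L
      ang_err <- c(ang_err, ang_diff_deg(candidates$angle_deg[j], truth$mu_deg[i]))
    }
  }
  tibble::tibble(
    n_true = n_true, n_detected = n_det, tp = tp,
    fp = n_det - tp, fn = n_true - tp,
    sensitivity = if (n_true > 0) tp / n_true else NA_real_,
    precision = if (n_det > 0) tp / n_det else NA_real_,
    mean_angle_err_deg = if (length(ang_err)) mean(ang_err) else NA_real_
  )
}
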