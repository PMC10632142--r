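#' Simulate soma mosaics with known spatial structure
#'
#' Generates 2D point patterns emulating retinal ganglion cell soma mosaics:
#' `"random"` draws uniform i.i.d. points (complete spatial randomness),
#' `"exclusion"` draws a hard-core pattern by dart throwing (no two somas
#' closer than `d_min_um`, as expected for a single cell type whose somas
#' tile the retina), and `"superposition"` overlays `n_mosaics` independent
#' hard-core mosaics, each at `density_per_mm2 / n_mosaics` — the situation
#' expected when an antibody labels several intermixed types.
#'
#' @param kind One of `"random"`, `"exclusion"`, `"superposition"`.
#' @param density_per_mm2 Total soma density, cells per mm^2.
#' @param region Sampling window `c(xmin, xmax, ymin, ymax)` in µm.
#' @param d_min_um Hard-core exclusion distance in µm (exclusion and
#'   superposition kinds).
#' @param n_mosaics Number of independent component mosaics (superposition).
#' @param n Optional exact point count; overrides `density_per_mm2 * area`.
#' @param seed Integer RNG seed; same seed reproduces the pattern exactly.
#' @return A tibble of class `point_mosaic` with columns `x_um`, `y_um`,
#'   `component` (component mosaic id, 1 for simple kinds), and attributes
#'   `region` (µm rectangle) and `seed`.
#' @examples
#' m <- synth_mosaic("exclusion", density_per_mm2 = 30,
#'                   region = c(0, 2000, 0, 2000), d_min_um = 100, seed = 1)
#' min(dist(cbind(m$x_um, m$y_um))) >= 100
#' @export
synth_mosaic <- function(kind = c("random", "exclusion", "superposition"),
                         density_per_mm2,
                         region,
                         d_min_um = NULL,
                         n_mosaics = 3,
                         n = NULL,
                         seed = 1) {
  kind <- match.arg(kind)
  check_rect(region)
  area_mm2 <- rect_area_um2(region) / UM2_PER_MM2
  n_target <- n %||% round(density_per_mm2 * area_mm2)
  if (n_target < 10) {
    abort("mosaic would contain fewer than 10 points; enlarge region or density")
  }
  set.seed(seed)
  pts <- switch(kind,
    random = tibble::tibble(
      x_um = runif(n_target, region[1], region[2]),
      y_um = runif(n_target, region[3], region[4]),
      component = 1L
    ),
    exclusion = {
      if (is.null(d_min_um)) abort("`d_min_um` is required for kind = 'exclusion'")
      xy <- hardcore_points(n_target, region, d_min_um)
      tibble::tibble(x_um = xy[, 1], y_um = xy[, 2], component = 1L)
    },
    superposition = {
      if (is.null(d_min_um)) abort("`d_min_um` is required for kind = 'superposition'")
      n_each <- round(n_target / n_mosaics)
      purrr::map_dfr(seq_len(n_mosaics), function(k) {
        xy <- hardcore_points(n_each, region, d_min_um)
        tibble::tibble(x_um = xy[, 1], y_um = xy[, 2], component = as.integer(k))
      })
    }
  )
  new_point_mosaic(pts, region = region, seed = seed)
}

new_point_mosaic <- function(pts, region, seed = NA_integer_) {
  out <- tibble::as_tibble(pts)
  attr(out, "region") <- region
  attr(out, "seed") <- seed
  class(out) <- c("point_mosaic", class(out))
  out
}

#' Construct a point mosaic from coordinates
#'
#' Wraps soma coordinates and their rectangular sampling window into the
#' container used by [voronoi_regularity()] and [density_recovery_profile()].
#'
#' @param data Data frame with columns `x_um`, `y_um` (and optionally
#'   `component` or `label`).
#' @param region Sampling window `c(xmin, xmax, ymin, ymax)` in µm.
#' @return A `point_mosaic` tibble.
#' @export
point_mosaic <- function(data, region) {
  check_rect(region)
  if (!all(c("x_um", "y_um") %in% names(data))) {
    abort("`data` must have columns x_um and y_um")
  }
  inside <- data$x_um >= region[1] & data$x_um <= region[2] &
    data$y_um >= region[3] & data$y_um <= region[4]
  if (!all(inside)) abort("all points must lie inside `region`")
  if (is.null(data[["component"]])) data$component <- 1L
  new_point_mosaic(data, region = region)
}

#' @export
print.point_mosaic <- function(x, ...) {
  region <- attr(x, "region")
  dens <- nrow(x) / (rect_area_um2(region) / UM2_PER_MM2)
  cat(sprintf("<point_mosaic> %d somas in %.0f x %.0f um window (%.2f cells/mm^2)\n",
              nrow(x), region[2] - region[1], region[4] - region[3], dens))
  NextMethod()
}

# dart-throwing hard-core sampler; budget 1e4 proposals per requested point
hardcore_points <- function(n, region, d_min_um) {
  d2 <- d_min_um^2
  pts <- matrix(NA_real_, n, 2)
  placed <- 0L
  budget <- 1e4 * n
  tries <- 0L
  while (placed < n && tries < budget) {
    tries <- tries + 1L
    p <- c(runif(1, region[1], region[2]), runif(1, region[3], region[4]))
    if (placed == 0L ||
        min((pts[seq_len(placed), 1] - p[1])^2 + (pts[seq_len(placed), 2] - p[2])^2) >= d2) {
      placed <- placed + 1L
      pts[placed, ] <- p
    }
  }
  if (placed < n) {
    abort(sprintf(
      "hard-core packing infeasible: placed %d of %d points (d_min = %g um)",
      placed, n, d_min_um
    ))
  }
  pts
}
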