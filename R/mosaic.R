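#' Voronoi domain regularity of a soma mosaic
#'
#' Tessellates the soma positions into Voronoi domains, clipped to the
#' rectangular sampling window, and computes the Voronoi domain regularity
#' index (VDRI): the mean domain area divided by the standard deviation of
#' domain areas. Domains intersecting the window boundary carry truncated,
#' uninformative areas and are excluded before the index is computed; a
#' domain is excluded when any of its vertices lies on or outside the
#' boundary (unbounded domains are always clipped to the boundary and hence
#' excluded). VDRI values of about 1.9 and below are what uniform random
#' point arrays produce; regular mosaics score higher.
#'
#' @param mosaic A [point_mosaic()] (or data frame with `x_um`, `y_um` plus
#'   a `region` argument).
#' @param region Sampling window, required when `mosaic` is a plain data
#'   frame.
#' @return A tibble of class `voronoi_result`, one row per soma, with
#'   columns `x_um`, `y_um`, `area_um2` (clipped domain area) and `excluded`
#'   (boundary flag). Attributes `vdri`, `n_retained`, `region`;
#'   see [glance.voronoi_result()].
#' @examples
#' m <- synth_mosaic("random", 20, c(0, 2000, 0, 2000), seed = 1)
#' glance(voronoi_regularity(m))
#' @export
voronoi_regularity <- function(mosaic, region = attr(mosaic, "region")) {
  check_rect(region)
  x <- mosaic$x_um
  y <- mosaic$y_um
  if (length(x) < 4) abort("Voronoi regularity needs at least 4 points")
  dd <- deldir::deldir(x, y, rw = region)
  areas <- dd$summary$dir.area
  # a domain intersects the window boundary iff one of its tessellation
  # edges is clipped by (or has a vertex on) the window rectangle
  sg <- dd$dirsgs
  eps <- 1e-8 * max(region[2] - region[1], region[4] - region[3])
  on_boundary <- function(px, py) {
    px <= region[1] + eps | px >= region[2] - eps |
      py <= region[3] + eps | py >= region[4] - eps
  }
  clipped <- sg$bp1 | sg$bp2 | on_boundary(sg$x1, sg$y1) | on_boundary(sg$x2, sg$y2)
  boundary_pts <- unique(c(sg$ind1[clipped], sg$ind2[clipped]))
  excluded <- seq_along(x) %in% boundary_pts
  if (all(excluded)) abort("all Voronoi domains intersect the boundary; window too small")
  kept <- areas[!excluded]
  s <- sd(kept)
  vdri <- if (length(kept) >= 2 && s > 0) mean(kept) / s else Inf
  out <- tibble::tibble(x_um = x, y_um = y, area_um2 = areas, excluded = excluded)
  attr(out, "vdri") <- vdri
  attr(out, "n_retained") <- length(kept)
  attr(out, "region") <- region
  class(out) <- c("voronoi_result", class(out))
  out
}

#' @export
print.voronoi_result <- function(x, ...) {
  cat(sprintf("<voronoi_result> VDRI = %.3f (%d of %d domains retained)\n",
              attr(x, "vdri"), attr(x, "n_retained"), nrow(x)))
  NextMethod()
}

#' Summarise a Voronoi tessellation
#'
#' @param x A `voronoi_result`.
#' @param ... Unused.
#' @return One-row tibble with `vdri`, `n_points`, `n_retained`,
#'   `mean_area_um2`, `sd_area_um2`.
#' @export
glance.voronoi_result <- function(x, ...) {
  kept <- x$area_um2[!x$excluded]
  tibble::tibble(
    vdri = attr(x, "vdri"),
    n_points = nrow(x),
    n_retained = attr(x, "n_retained"),
    mean_area_um2 = mean(kept),
    sd_area_um2 = sd(kept)
  )
}

#' Random-mosaic null distribution of the VDRI
#'
#' Simulates uniform random mosaics at matched point count and window and
#' computes the VDRI of each, giving the null distribution against which an
#' observed mosaic's regularity is judged.
#'
#' @param n Number of points per simulation (matched to the observed mosaic).
#' @param region Sampling window `c(xmin, xmax, ymin, ymax)` in µm.
#' @param n_sims Number of simulations.
#' @param seed Integer seed; simulation `i` uses a seed derived from it.
#' @param observed Optional observed VDRI; its empirical quantile within the
#'   null is then reported by [glance.vdri_null()].
#' @return Tibble of class `vdri_null` with columns `sim`, `seed`, `vdri`.
#' @export
random_null_vdri <- function(n, region, n_sims = 200, seed = 1, observed = NULL) {
  check_rect(region)
  if (n_sims < 1) abort("`n_sims` must be >= 1")
  if (n_sims == 1) warn("n_sims = 1 gives a degenerate null summary")
  sims <- purrr::map_dfr(seq_len(n_sims), function(i) {
    s <- derive_seed(seed, i)
    m <- synth_mosaic("random", density_per_mm2 = NA, region = region, n = n, seed = s)
    tibble::tibble(sim = i, seed = s, vdri = attr(voronoi_regularity(m), "vdri"))
  })
  attr(sims, "observed") <- observed
  class(sims) <- c("vdri_null", class(sims))
  sims
}

#' Summarise a VDRI null distribution
#'
#' @param x A `vdri_null`.
#' @param ... Unused.
#' @return One-row tibble with the null mean, sd, 5th/95th percentiles and,
#'   if an observed VDRI was supplied, its empirical quantile and the
#'   one-sided empirical p-value for regularity (P(null >= observed)).
#' @export
glance.vdri_null <- function(x, ...) {
  obs <- attr(x, "observed")
  out <- tibble::tibble(
    n_sims = nrow(x),
    mean_vdri = mean(x$vdri),
    sd_vdri = sd(x$vdri),
    q05 = unname(quantile(x$vdri, 0.05)),
    q95 = unname(quantile(x$vdri, 0.95))
  )
  if (!is.null(obs)) {
    out$observed <- obs
    out$quantile <- mean(x$vdri < obs)
    out$p_regular <- (sum(x$vdri >= obs) + 1) / (nrow(x) + 1)
  }
  out
}

# --- density recovery profile ---------------------------------------------

# area of disc (center cx,cy, radius r) intersected with the quadrant
# {x >= a, y >= b} for a disc centred at the origin; a, b vectors
quadrant_disc_area <- function(a, b, r) {
  if (r <= 0) return(rep(0, length(a)))
  s <- function(d) sqrt(pmax(r^2 - d^2, 0))
  seg <- function(d) {
    # area of disc with x >= d
    dc <- pmin(pmax(d, -r), r)
    ifelse(d >= r, 0, r^2 * acos(dc / r) - dc * s(dc))
  }
  inside <- a^2 + b^2 < r^2
  # corner inside the disc: sector between the two boundary crossings plus
  # the two triangles closing the region at the corner
  th_a <- atan2(s(a), a)
  th_b <- atan2(b, s(b))
  area_in <- r^2 * (th_a - th_b) / 2 + (2 * a * b - a * s(a) - b * s(b)) / 2
  area_out <- ifelse(
    a >= 0 & b >= 0, 0,
    ifelse(a >= 0, seg(a),
      ifelse(b >= 0, seg(b), seg(a) + seg(b) - pi * r^2)
    )
  )
  ifelse(inside, area_in, pmax(area_out, 0))
}

# area of disc(cx, cy, r) within rectangle region = c(x1, x2, y1, y2);
# cx, cy may be vectors
disc_rect_area <- function(cx, cy, r, region) {
  a1 <- region[1] - cx
  a2 <- region[2] - cx
  b1 <- region[3] - cy
  b2 <- region[4] - cy
  quadrant_disc_area(a1, b1, r) - quadrant_disc_area(a2, b1, r) -
    quadrant_disc_area(a1, b2, r) + quadrant_disc_area(a2, b2, r)
}

#' Density recovery profile of a soma mosaic
#'
#' Computes the Rodieck density recovery profile: the density of neighbouring
#' somas as a function of distance from each soma, averaged over all somas.
#' Counts in each 20-µm annulus are divided by the summed annulus areas,
#' with each annulus analytically clipped to the rectangular sampling window
#' so that border somas do not bias the densities. A central "well" of low
#' density reveals an exclusion zone, the signature of a single-type mosaic;
#' its depth is summarised as the convergence percentage: the mean of the 3
#' lowest bin densities (the first bin is excluded as unreliable, its annulus
#' area being tiny) as a percentage of the plateau density at 390-1,000 µm.
#'
#' @param mosaic A [point_mosaic()].
#' @param r_max_um,bin_um Profile extent and bin width in µm (defaults
#'   1,000 and 20).
#' @param region Sampling window; defaults to the mosaic's.
#' @return Tibble of class `drp_profile` with columns `r_lo_um`, `r_hi_um`,
#'   `r_mid_um`, `count`, `area_mm2`, `density_per_mm2`, `excluded` (first
#'   bin flag). Attributes `well_density`, `plateau_density`,
#'   `convergence_pct`, `n_points`, `mean_density_per_mm2`;
#'   see [glance.drp_profile()].
#' @export
density_recovery_profile <- function(mosaic, r_max_um = 1000, bin_um = 20,
                                     region = attr(mosaic, "region")) {
  check_rect(region)
  x <- mosaic$x_um
  y <- mosaic$y_um
  n <- length(x)
  if (n < 10) abort("density recovery profile needs at least 10 points")
  if (r_max_um > max(region[2] - region[1], region[4] - region[3])) {
    warn("profile radius exceeds window size; outer annuli are heavily clipped")
  }
  edges <- seq(0, r_max_um, by = bin_um)
  n_bins <- length(edges) - 1
  d <- as.vector(dist(cbind(x, y)))
  idx <- findInterval(d, edges, rightmost.closed = TRUE)
  counts <- 2 * tabulate(idx[idx >= 1 & idx <= n_bins], nbins = n_bins)
  # summed annulus area over reference points, clipped to the window
  disc_areas <- vapply(edges, function(r) sum(disc_rect_area(x, y, r, region)),
                       numeric(1))
  ann_um2 <- diff(disc_areas)
  density <- counts / ann_um2 * UM2_PER_MM2
  out <- tibble::tibble(
    r_lo_um = edges[-length(edges)],
    r_hi_um = edges[-1],
    r_mid_um = (edges[-1] + edges[-length(edges)]) / 2,
    count = counts,
    area_mm2 = ann_um2 / UM2_PER_MM2,
    density_per_mm2 = density,
    excluded = c(TRUE, rep(FALSE, n_bins - 1))
  )
  usable <- !out$excluded
  well <- mean(sort(out$density_per_mm2[usable])[1:3])
  plateau <- mean(out$density_per_mm2[out$r_mid_um >= 390])
  attr(out, "well_density") <- well
  attr(out, "plateau_density") <- plateau
  attr(out, "convergence_pct") <- 100 * well / plateau
  attr(out, "n_points") <- n
  attr(out, "mean_density_per_mm2") <- n / (rect_area_um2(region) / UM2_PER_MM2)
  attr(out, "region") <- region
  class(out) <- c("drp_profile", class(out))
  out
}

#' @export
print.drp_profile <- function(x, ...) {
  cat(sprintf("<drp_profile> %d points; well %.2f, plateau %.2f cells/mm^2 (convergence %.1f%%)\n",
              attr(x, "n_points"), attr(x, "well_density"),
              attr(x, "plateau_density"), attr(x, "convergence_pct")))
  NextMethod()
}

#' Summarise a density recovery profile
#'
#' @param x A `drp_profile`.
#' @param ... Unused.
#' @return One-row tibble with `well_density`, `plateau_density`,
#'   `convergence_pct`, `n_points`, `mean_density_per_mm2`.
#' @export
glance.drp_profile <- function(x, ...) {
  tibble::tibble(
    well_density = attr(x, "well_density"),
    plateau_density = attr(x, "plateau_density"),
    convergence_pct = attr(x, "convergence_pct"),
    n_points = attr(x, "n_points"),
    mean_density_per_mm2 = attr(x, "mean_density_per_mm2")
  )
}

#' Dendritic coverage factor
#'
#' Spatial density of a cell type multiplied by its mean dendritic field
#' area. A value of 1 means the dendritic arbours exactly tile the retina;
#' larger values indicate overlap.
#'
#' @param density_per_mm2 Cell density, cells per mm^2.
#' @param dendritic_area_mm2 Mean dendritic field area, mm^2 per cell.
#' @return The coverage factor (dimensionless).
#' @examples
#' coverage_factor(10, 0.1) # 1: exact tiling
#' @export
coverage_factor <- function(density_per_mm2, dendritic_area_mm2) {
  if (any(density_per_mm2 < 0) || any(dendritic_area_mm2 < 0)) {
    abort("density and dendritic area must be non-negative")
  }
  density_per_mm2 * dendritic_area_mm2
}

#' Gridded soma density with neighbour imputation
#'
#' Divides the sampling window into square cells (default 500 µm) and
#' reports soma density per cell. Cells flagged as unusable (poor focus,
#' damaged tissue) are imputed as the mean of their valid 8-neighbours.
#'
#' @param mosaic A [point_mosaic()].
#' @param cell_um Grid cell side, µm. Only cells fully inside the window are
#'   formed.
#' @param bad_cells Optional data frame with columns `row`, `col` of cells
#'   whose counts are unusable.
#' @param region Sampling window; defaults to the mosaic's.
#' @return Tibble with `row`, `col`, cell-centre coordinates, `n`,
#'   `density_per_mm2` and `imputed`.
#' @export
density_grid <- function(mosaic, cell_um = 500, bad_cells = NULL,
                         region = attr(mosaic, "region")) {
  check_rect(region)
  n_col <- floor((region[2] - region[1]) / cell_um)
  n_row <- floor((region[4] - region[3]) / cell_um)
  if (n_col < 1 || n_row < 1) abort("region smaller than one grid cell")
  col <- floor((mosaic$x_um - region[1]) / cell_um) + 1
  row <- floor((mosaic$y_um - region[3]) / cell_um) + 1
  keep <- col >= 1 & col <= n_col & row >= 1 & row <= n_row
  counts <- matrix(0, n_row, n_col)
  for (i in which(keep)) counts[row[i], col[i]] <- counts[row[i], col[i]] + 1
  dens <- counts / (cell_um^2 / UM2_PER_MM2)
  bad <- matrix(FALSE, n_row, n_col)
  if (!is.null(bad_cells)) {
    for (i in seq_len(nrow(bad_cells))) {
      bad[bad_cells$row[i], bad_cells$col[i]] <- TRUE
    }
  }
  imputed <- dens
  for (r in seq_len(n_row)) {
    for (cc in seq_len(n_col)) {
      if (bad[r, cc]) {
        rr <- max(1, r - 1):min(n_row, r + 1)
        cs <- max(1, cc - 1):min(n_col, cc + 1)
        nb <- expand.grid(r = rr, c = cs)
        nb <- nb[!(nb$r == r & nb$c == cc), ]
        good <- !bad[cbind(nb$r, nb$c)]
        if (!any(good)) {
          warn(sprintf("grid cell (%d, %d) has no valid neighbour; left missing", r, cc))
          imputed[r, cc] <- NA_real_
        } else {
          imputed[r, cc] <- mean(dens[cbind(nb$r, nb$c)][good])
        }
      }
    }
  }
  tidyr::expand_grid(row = seq_len(n_row), col = seq_len(n_col)) |>
    dplyr::mutate(
      x_mid_um = region[1] + (.data$col - 0.5) * cell_um,
      y_mid_um = region[3] + (.data$row - 0.5) * cell_um,
      n = counts[cbind(.data$row, .data$col)],
      density_per_mm2 = imputed[cbind(.data$row, .data$col)],
      imputed = bad[cbind(.data$row, .data$col)]
    )
}

#' Equivalent eccentricity in nasal retina
#'
#' Nasal retinal distances are foreshortened relative to temporal ones; the
#' equivalent (temporal-matched) eccentricity of a nasal-retina location is
#' sqrt((0.61 x)^2 + y^2), with `x` the distance in mm nasal to the foveal
#' centre and `y` the vertical (superior/inferior) distance in mm.
#'
#' @param x_mm_nasal Nasal distance from the foveal centre, mm.
#' @param y_mm_vertical Vertical distance from the foveal centre, mm.
#' @return Equivalent eccentricity in mm.
#' @examples
#' equivalent_eccentricity(10, 0) # 6.1
#' @export
equivalent_eccentricity <- function(x_mm_nasal, y_mm_vertical) {
  sqrt((0.61 * x_mm_nasal)^2 + y_mm_vertical^2)
}
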