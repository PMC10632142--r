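#' Dendritic stratification depth profile
#'
#' Turns a z-axis intensity profile of a dendritic arbour into an IPL depth
#' profile: the mean background is subtracted, negative values are set to
#' 0, intensities are normalized to their maximum, and the z axis is mapped
#' linearly so that the INL border is 0% and the GCL border 100% (the
#' mapping flips automatically if the stack was acquired in the opposite
#' direction).
#'
#' @param profile Data frame with a `z_um` column and one intensity column
#'   per channel.
#' @param inl_z_um,gcl_z_um z positions of the INL and GCL borders (must
#'   differ).
#' @param background Scalar background intensity, or named vector per
#'   channel.
#' @param channels Intensity column names; defaults to all non-`z_um`
#'   columns.
#' @return A tibble of class `depth_profile`, long format: `depth_pct`,
#'   `channel`, `intensity` (in `[0, 1]`). Peak depths per channel are in
#'   the `peaks` attribute (tibble `channel`, `peak_depth_pct`; `NA` with a
#'   flag when a channel is entirely below background).
#' @export
depth_profile <- function(profile, inl_z_um, gcl_z_um, background = 0,
                          channels = setdiff(names(profile), "z_um")) {
  if (inl_z_um == gcl_z_um) abort("INL and GCL border positions must differ")
  depth <- 100 * (profile$z_um - inl_z_um) / (gcl_z_um - inl_z_um)
  bg <- if (length(background) == 1) setNames(rep(background, length(channels)), channels)
        else background
  long <- purrr::map_dfr(channels, function(ch) {
    v <- pmax(profile[[ch]] - bg[[ch]], 0)
    if (max(v) > 0) v <- v / max(v)
    tibble::tibble(depth_pct = depth, channel = ch, intensity = v)
  })
  peaks <- long |>
    dplyr::group_by(.data$channel) |>
    dplyr::summarise(
      all_below_background = max(.data$intensity) == 0,
      peak_depth_pct = if (max(.data$intensity) == 0) NA_real_ else
        .data$depth_pct[which.max(.data$intensity)],
      .groups = "drop"
    )
  if (any(peaks$all_below_background)) {
    warn("some channels are entirely below background; peak depth undefined")
  }
  long <- dplyr::arrange(long, .data$channel, .data$depth_pct)
  attr(long, "peaks") <- peaks
  class(long) <- c("depth_profile", class(long))
  long
}

#' Peak stratification depths of a profile
#' @param profile A [depth_profile()].
#' @return Tibble `channel`, `peak_depth_pct`, `all_below_background`.
#' @export
peak_depths <- function(profile) attr(profile, "peaks")

#' Co-fasciculation contact fraction between two binary volumes
#'
#' Uses the reference channel (e.g. a DiI-filled cell's dendritic mask) to
#' mask the partner channel (e.g. thresholded ChAT staining) slice by
#' slice; overlapping areas are summed over slices and expressed as a
#' percentage of the total reference area. As a chance-level control the
#' partner channel can additionally be rotated by 90 degrees in-plane about
#' the volume centre (nearest-neighbour resampling; voxels rotated out of
#' frame are dropped) and the overlap recomputed.
#'
#' @param mask_ref,mask_partner Logical (or 0/1) arrays of identical shape
#'   `Y x X x Z`.
#' @param rotate_control Also compute the rotated-partner control.
#' @return A list of class `contact_result`: `per_slice` tibble (`slice`,
#'   `ref_area`, `overlap_area`, `rotated_overlap_area`),
#'   `total_overlap_pct`, `rotated_overlap_pct` (`NA` unless requested),
#'   `partner_area_kept_pct` (partner voxels surviving rotation).
#' @export
contact_fraction <- function(mask_ref, mask_partner, rotate_control = TRUE) {
  if (!identical(dim(mask_ref), dim(mask_partner))) {
    abort("reference and partner volumes must have identical shapes")
  }
  if (length(dim(mask_ref)) != 3) abort("masks must be Y x X x Z arrays")
  ref <- mask_ref != 0
  par <- mask_partner != 0
  if (!any(ref)) abort("reference mask is empty")
  nz <- dim(ref)[3]
  rot <- if (rotate_control) rotate90_inplane(par) else NULL
  per_slice <- purrr::map_dfr(seq_len(nz), function(z) {
    tibble::tibble(
      slice = z,
      ref_area = sum(ref[, , z]),
      overlap_area = sum(ref[, , z] & par[, , z]),
      rotated_overlap_area = if (is.null(rot)) NA_integer_ else
        sum(ref[, , z] & rot[, , z])
    )
  })
  total_ref <- sum(per_slice$ref_area)
  structure(
    list(
      per_slice = per_slice,
      total_overlap_pct = 100 * sum(per_slice$overlap_area) / total_ref,
      rotated_overlap_pct = if (is.null(rot)) NA_real_ else
        100 * sum(per_slice$rotated_overlap_area) / total_ref,
      partner_area_kept_pct = if (is.null(rot)) NA_real_ else
        100 * sum(rot) / max(sum(par), 1)
    ),
    class = "contact_result"
  )
}

#' @export
print.contact_result <- function(x, ...) {
  cat(sprintf("<contact_result> overlap %.2f%% of reference area", x$total_overlap_pct))
  if (!is.na(x$rotated_overlap_pct)) {
    cat(sprintf(" (rotated control %.2f%%)", x$rotated_overlap_pct))
  }
  cat("\n")
  invisible(x)
}

# 90-degree in-plane rotation about the volume centre, nearest neighbour;
# exact (area conserving) for square slices
rotate90_inplane <- function(vol) {
  d <- dim(vol)
  out <- array(FALSE, d)
  cy <- (d[1] + 1) / 2
  cx <- (d[2] + 1) / 2
  # target (y, x) pulls from source rotated -90: (y0, x0) = (cy + (x - cx), cx - (y - cy))
  yy <- rep(seq_len(d[1]), times = d[2])
  xx <- rep(seq_len(d[2]), each = d[1])
  y0 <- round(cy + (xx - cx))
  x0 <- round(cx - (yy - cy))
  ok <- y0 >= 1 & y0 <= d[1] & x0 >= 1 & x0 <= d[2]
  for (z in seq_len(d[3])) {
    sl <- matrix(FALSE, d[1], d[2])
    sl[cbind(yy[ok], xx[ok])] <- vol[cbind(y0[ok], x0[ok], z)]
    out[, , z] <- sl
  }
  out
}

#' Synthetic wrap-around dendrite volumes
#'
#' Generates a pair of binary volumes emulating co-fasciculating dendrites:
#' the reference channel contains straight dendrite segments at random
#' orientations through the mid-plane, and the partner channel is drawn as
#' a tube around (wrapping) those same segments, plus unrelated background
#' processes. Contact between the channels is therefore far above chance in
#' the normal orientation and near chance after a 90-degree rotation.
#'
#' @param size Edge length of the (square) slices, voxels.
#' @param n_slices Number of z slices.
#' @param n_segments Number of reference dendrite segments.
#' @param wrap_radius Partner tube radius around each segment, voxels.
#' @param n_background Number of unrelated partner segments.
#' @param seed Integer seed.
#' @return List with logical arrays `ref` and `partner` (`size x size x
#'   n_slices`).
#' @export
synth_dendrite_volumes <- function(size = 64, n_slices = 5, n_segments = 4,
                                   wrap_radius = 2, n_background = 6,
                                   seed = 1) {
  set.seed(seed)
  ref <- array(FALSE, c(size, size, n_slices))
  partner <- array(FALSE, c(size, size, n_slices))
  zmid <- ceiling(n_slices / 2)
  draw_segment <- function(vol, z, width) {
    th <- runif(1, 0, pi)
    x0 <- runif(1, size * 0.2, size * 0.8)
    y0 <- runif(1, size * 0.2, size * 0.8)
    tt <- seq(-size, size, by = 0.5)
    xs <- round(x0 + tt * cos(th))
    ys <- round(y0 + tt * sin(th))
    ok <- xs >= 1 & xs <= size & ys >= 1 & ys <= size
    for (w in -width:width) {
      xw <- pmin(pmax(xs[ok] + w, 1), size)
      vol[cbind(ys[ok], xw, z)] <- TRUE
      yw <- pmin(pmax(ys[ok] + w, 1), size)
      vol[cbind(yw, xs[ok], z)] <- TRUE
    }
    vol
  }
  for (i in seq_len(n_segments)) {
    th <- runif(1, 0, pi)
    x0 <- runif(1, size * 0.25, size * 0.75)
    y0 <- runif(1, size * 0.25, size * 0.75)
    tt <- seq(-size, size, by = 0.5)
    xs <- round(x0 + tt * cos(th))
    ys <- round(y0 + tt * sin(th))
    ok <- xs >= 1 & xs <= size & ys >= 1 & ys <= size
    ref[cbind(ys[ok], xs[ok], zmid)] <- TRUE
    # partner wraps the segment in the neighbouring slices and laterally
    for (dz in -1:1) {
      z <- zmid + dz
      if (z < 1 || z > n_slices) next
      for (w in -wrap_radius:wrap_radius) {
        xw <- pmin(pmax(xs[ok] + w, 1), size)
        yw <- pmin(pmax(ys[ok] + w, 1), size)
        partner[cbind(ys[ok], xw, z)] <- TRUE
        partner[cbind(yw, xs[ok], z)] <- TRUE
      }
    }
  }
  for (i in seq_len(n_background)) {
    z <- sample(n_slices, 1)
    partner <- draw_segment(partner, z, width = 1)
  }
  list(ref = ref, partner = partner)
}
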