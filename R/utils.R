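#' @importFrom rlang abort warn .data
#' @importFrom stats sd median quantile rnorm runif rnbinom kmeans wilcox.test
#'   coef predict setNames complete.cases
#' @importFrom utils head tail
NULL

# µm <-> mm^2 conversion used everywhere densities are reported
UM2_PER_MM2 <- 1e6

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Retinal magnification constant for the macaque eye
#'
#' Conversion factor between retinal distance and visual angle, 223 µm of
#' retina per degree of visual angle.
#' @export
UM_PER_DEG_MACAQUE <- 223

#' Convert between retinal speed and angular speed
#'
#' Drifting-bar speeds are specified on the retina in µm/s; the equivalent
#' angular speed uses the retinal magnification factor (223 µm/degree for
#' the macaque eye).
#'
#' @param um_s Speed on the retina, µm/s.
#' @param deg_s Angular speed, degrees/s.
#' @param um_per_deg Magnification factor, µm of retina per degree.
#' @return A numeric vector of converted speeds.
#' @examples
#' um_s_to_deg_s(500) # 2.24 deg/s
#' @export
um_s_to_deg_s <- function(um_s, um_per_deg = UM_PER_DEG_MACAQUE) {
  stopifnot(um_per_deg > 0)
  um_s / um_per_deg
}

#' @rdname um_s_to_deg_s
#' @export
deg_s_to_um_s <- function(deg_s, um_per_deg = UM_PER_DEG_MACAQUE) {
  stopifnot(um_per_deg > 0)
  deg_s * um_per_deg
}

# wrap angles into [0, 360)
wrap_deg <- function(x) ((x %% 360) + 360) %% 360

# circular difference in degrees, result in [0, 180]
ang_diff_deg <- function(a, b) {
  d <- abs(wrap_deg(a) - wrap_deg(b))
  pmin(d, 360 - d)
}

# shoelace polygon area (vertices in order, not closed)
polygon_area <- function(x, y) {
  n <- length(x)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

# derive a stream-specific 32-bit seed from a master seed
derive_seed <- function(seed, stream) {
  (seed * 7919L + stream * 104729L) %% 2147483647L
}

is_rect <- function(region) {
  is.numeric(region) && length(region) == 4 &&
    region[2] > region[1] && region[4] > region[3]
}

check_rect <- function(region) {
  if (!is_rect(region)) {
    abort("`region` must be c(xmin, xmax, ymin, ymax) with xmax > xmin, ymax > ymin")
  }
  invisible(region)
}

rect_area_um2 <- function(region) {
  (region[2] - region[1]) * (region[4] - region[3])
}
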