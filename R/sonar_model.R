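#' Sonar acquisition geometry
#'
#' Describes one 360-degree mechanical-scanning sonar: how many bearing bins
#' make up a revolution, how many range samples are taken per bearing, the
#' range resolution, the revolution period, and the radius of the central
#' exclusion zone occupied by the ensonified structure and its self-echo.
#' `max_range` is derived as `n_range_bins * range_resolution`.
#'
#' Defaults describe a unit with a 10 m range at 0.05 m resolution and an
#' 8 s revolution, the configuration class of the Ping360-style sonars used
#' to monitor fish around a centred structure in a net pen.
#'
#' @param n_bearings Number of bearing bins per revolution (>= 8).
#' @param n_range_bins Number of range samples per bearing (>= 2).
#' @param range_resolution Metres per range bin (> 0).
#' @param scan_period Seconds per full revolution.
#' @param exclusion_radius Metres; echoes at or below this radius belong to
#'   the structure / self-echo zone and are ignored by the analysis.
#' @return An object of class `sonar_config`.
#' @export
#' @examples
#' cfg <- sonar_config()
#' cfg$max_range
sonar_config <- function(n_bearings = 400L, n_range_bins = 200L,
                         range_resolution = 0.05, scan_period = 8,
                         exclusion_radius = 0.5) {
  n_bearings <- as.integer(n_bearings)
  n_range_bins <- as.integer(n_range_bins)
  if (n_bearings < 8L) stop("n_bearings must be >= 8")
  if (n_range_bins < 2L) stop("n_range_bins must be >= 2")
  if (range_resolution <= 0) stop("range_resolution must be > 0")
  if (scan_period <= 0) stop("scan_period must be > 0")
  max_range <- n_range_bins * range_resolution
  if (exclusion_radius < 0 || exclusion_radius >= max_range)
    stop("exclusion_radius must be in [0, max_range)")
  structure(
    list(n_bearings = n_bearings, n_range_bins = n_range_bins,
         range_resolution = range_resolution, max_range = max_range,
         scan_period = scan_period, exclusion_radius = exclusion_radius),
    class = "sonar_config")
}

#' @export
print.sonar_config <- function(x, ...) {
  cat(sprintf(
    "<sonar_config> %d bearings x %d range bins, %.3f m/bin (max %.1f m), %g s/rev, exclusion %.2f m\n",
    x$n_bearings, x$n_range_bins, x$range_resolution, x$max_range,
    x$scan_period, x$exclusion_radius))
  invisible(x)
}

#' One sonar revolution in (bearing, range) echo space
#'
#' @param config A [sonar_config()].
#' @param intensities Numeric matrix `[n_bearings x n_range_bins]` of
#'   non-negative echo strengths; defaults to all-zero.
#' @param t_start Trial-clock time (seconds) at the start of the revolution.
#' @return An object of class `scan_frame`.
#' @export
scan_frame <- function(config, intensities = NULL, t_start = 0) {
  stopifnot(inherits(config, "sonar_config"))
  if (is.null(intensities))
    intensities <- matrix(0, config$n_bearings, config$n_range_bins)
  if (!is.matrix(intensities) ||
      nrow(intensities) != config$n_bearings ||
      ncol(intensities) != config$n_range_bins)
    stop("intensities must be an [n_bearings x n_range_bins] matrix")
  if (any(intensities < 0)) stop("intensities must be non-negative")
  structure(list(config = config, intensities = intensities,
                 t_start = t_start),
            class = "scan_frame")
}

# Bearing angles (radians) at bin centres; bearing bin 1 points along +x,
# angles increase counter-clockwise.
bearing_angles <- function(config) {
  2 * pi * (seq_len(config$n_bearings) - 1L) / config$n_bearings
}

# Range (m) at bin centres.
range_centres <- function(config) {
  (seq_len(config$n_range_bins) - 0.5) * config$range_resolution
}

# Linear pixel index for every (bearing, range) bin of `config` on a square
# raster of side `side` centred at pixel `c0` with scale `mpp`.  The raster
# is indexed [x, y] with the y axis pointing up.
polar_pixel_index <- function(config, mpp, side, c0) {
  theta <- bearing_angles(config)
  r <- range_centres(config)
  ix <- c0 + round(outer(cos(theta), r) / mpp)
  iy <- c0 + round(outer(sin(theta), r) / mpp)
  (iy - 1L) * side + ix
}

#' Render a sonar revolution to a centred circular-scan image
#'
#' Paints each (bearing, range) echo sample onto a square raster centred on
#' the sonar/structure axis: the sample at bearing `theta` and range `r`
#' lands on the pixel nearest `centre + (r cos(theta), r sin(theta)) / mpp`.
#' Samples mapping to the same pixel combine by maximum (presence
#' semantics).  Bearing 0 points along +x, angles increase
#' counter-clockwise, and the image y axis points up; the raster side is
#' odd so the sonar axis is a single centre pixel.  Pixels beyond
#' `max_range` are exactly zero.
#'
#' @param frame A [scan_frame()].
#' @param metres_per_pixel Raster scale (m/px); must be positive and no
#'   coarser than the sonar's range resolution.
#' @return An object of class `circular_scan` with fields `pixels` (square
#'   matrix indexed `[x, y]`), `centre` (pixel index of the axis on both
#'   axes), `metres_per_pixel`, `t_start`, `t_end`, `config`.
#' @export
#' @examples
#' cfg <- sonar_config(n_bearings = 16, n_range_bins = 10)
#' fr <- scan_frame(cfg)
#' fr$intensities[1, 5] <- 1   # bearing 0, range 0.225 m
#' img <- render_frame(fr, metres_per_pixel = 0.05)
render_frame <- function(frame, metres_per_pixel = frame$config$range_resolution) {
  stopifnot(inherits(frame, "scan_frame"))
  cfg <- frame$config
  if (!is.numeric(metres_per_pixel) || metres_per_pixel <= 0)
    stop("metres_per_pixel must be > 0")
  if (metres_per_pixel > cfg$range_resolution)
    stop("metres_per_pixel must not exceed the sonar range resolution")
  half <- floor(cfg$max_range / metres_per_pixel)
  side <- 2L * half + 1L
  c0 <- half + 1L
  idx <- polar_pixel_index(cfg, metres_per_pixel, side, c0)
  pix <- numeric(side * side)
  v <- as.vector(frame$intensities)
  nz <- which(v > 0)
  if (length(nz)) {
    # ascending assignment: the last (largest) write wins == pixelwise max
    ord <- nz[order(v[nz])]
    pix[idx[ord]] <- v[ord]
  }
  structure(
    list(pixels = matrix(pix, side, side), centre = c0,
         metres_per_pixel = metres_per_pixel,
         t_start = frame$t_start, t_end = frame$t_start + cfg$scan_period,
         config = cfg),
    class = "circular_scan")
}

#' Sample a circular-scan image back onto the (bearing, range) grid
#'
#' Inverse-direction plumbing used for round-trip checks and for running
#' bearing-wise analyses on accumulated rasters: each (bearing, range) bin
#' of `config` takes the value of the nearest pixel.
#'
#' @param image A `circular_scan` (or any object with `pixels`, `centre`,
#'   `metres_per_pixel`).
#' @param config A [sonar_config()] consistent with the image extent.
#' @return Numeric matrix `[n_bearings x n_range_bins]`.
#' @export
image_to_polar <- function(image, config = image$config) {
  stopifnot(is.matrix(image$pixels))
  side <- nrow(image$pixels)
  if (side != ncol(image$pixels)) stop("image raster must be square")
  idx <- polar_pixel_index(config, image$metres_per_pixel, side,
                           image$centre)
  if (any(idx < 1L) || any(idx > side * side))
    stop("image centre/scale inconsistent with config (polar grid leaves raster)")
  matrix(image$pixels[idx], config$n_bearings, config$n_range_bins)
}

# Matrix of pixel centre distances (m) from the image centre, same
# [x, y] layout as the raster.
pixel_radius_m <- function(image) {
  side <- nrow(image$pixels)
  d <- seq_len(side) - image$centre
  sqrt(outer(d^2, d^2, `+`)) * image$metres_per_pixel
}
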