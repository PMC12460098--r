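#' Parameters of the classical (deterministic) segmentation backend
#'
#' @param echo_threshold Absolute intensity threshold separating echoes
#'   from background; `NULL` (default) derives it by Otsu's method from
#'   the pixels outside the exclusion zone.
#' @param coverage_min Minimum fraction of bearings that must show an
#'   echo beyond the exclusion radius for the image to contain a fish
#'   pattern; below it the school is deemed out of sonar range.
#' @param noise_max Maximal admissible fraction of above-threshold pixels
#'   inside the (radially eroded) fish-free region; above it the image is
#'   invalid (no coherent annular pattern).
#' @param smooth_window Odd number of bearing bins for the circular
#'   running-median smoothing of the inner-radius profile.
#' @param erode_px Radial erosion margin (pixels) applied to the fitted
#'   region before the noise test, so boundary-hugging echo pixels that
#'   the median smoother legitimately leaves on either side of the fitted
#'   contour do not count as noise.
#' @param min_region_px Minimum pixel count of the eroded fish-free
#'   annulus for a pattern call; a region that collapses onto the
#'   exclusion zone means echoes everywhere, i.e. an invalid image.
#' @return An object of class `seg_params`.
#' @export
seg_params <- function(echo_threshold = NULL, coverage_min = 0.05,
                       noise_max = 0.02, smooth_window = 9L,
                       erode_px = 3, min_region_px = 50L) {
  if (coverage_min < 0 || coverage_min > 1 || noise_max < 0 || noise_max > 1)
    stop("coverage_min and noise_max must be fractions in [0, 1]")
  smooth_window <- as.integer(smooth_window)
  if (smooth_window < 1L || smooth_window %% 2L == 0L)
    stop("smooth_window must be odd and >= 1")
  structure(list(echo_threshold = echo_threshold,
                 coverage_min = coverage_min, noise_max = noise_max,
                 smooth_window = smooth_window, erode_px = erode_px,
                 min_region_px = as.integer(min_region_px)),
            class = "seg_params")
}

# Circular running median of x with an odd window.
circular_median <- function(x, window) {
  if (window <= 1L) return(x)
  n <- length(x)
  h <- (window - 1L) %/% 2L
  idx <- outer(seq_len(n), -h:h, `+`)
  idx <- (idx - 1L) %% n + 1L
  apply(matrix(x[idx], n), 1, stats::median)
}

# Automatic echo threshold for the annulus pixels (exclusion < r <=
# max_range).  Otsu's threshold is only meaningful when the histogram is
# genuinely bimodal (echoes over background); on a unimodal image Otsu
# simply splits the noise.  The guard: accept the Otsu threshold only
# when the mean above/below contrast exceeds `sep_min` (echo blobs are
# an order of magnitude brighter than background; splitting a unimodal
# exponential yields a contrast around 8).  For a unimodal image the
# structure self-echo inside the exclusion zone serves as intensity
# reference: an annulus much darker than the structure has no echoes at
# all (threshold Inf -> out_of_range via the coverage rule), while an
# annulus as bright as the structure is saturated noise (keep the Otsu
# split; the collapsed fish-free region then yields invalid).
annulus_threshold <- function(image, sep_min = 15) {
  r <- pixel_radius_m(image)
  cfg <- image$config
  v <- image$pixels[r > cfg$exclusion_radius & r <= cfg$max_range]
  vmax <- max(v)
  if (vmax <= 0) return(Inf)
  thr <- vmax * EBImage::otsu(matrix(v / vmax, 1), range = c(0, 1))
  lo <- mean(v[v <= thr])
  sep <- if (lo > 0) mean(v[v > thr]) / lo else Inf
  if (sep >= sep_min) return(thr)
  ref <- suppressWarnings(max(image$pixels[r <= cfg$exclusion_radius]))
  if (is.finite(ref) && ref > 0 && vmax < 0.5 * ref) Inf else thr
}

# Bearing bin (1-based) of every pixel under the image's polar convention.
pixel_bearing_bin <- function(image) {
  side <- nrow(image$pixels)
  d <- seq_len(side) - image$centre
  dx <- matrix(d, side, side)                # varies along x (rows)
  dy <- matrix(d, side, side, byrow = TRUE)  # varies along y (cols)
  ang <- atan2(dy, dx)
  nb <- image$config$n_bearings
  (round(ang / (2 * pi) * nb)) %% nb + 1L
}

new_segmentation_mask <- function(category, fish_free, image, backend,
                                  extra = list()) {
  structure(
    c(list(category = category, fish_free = fish_free,
           centre = image$centre, metres_per_pixel = image$metres_per_pixel,
           config = image$config, meta = image$meta, backend = backend),
      extra),
    class = "segmentation_mask")
}

#' @export
print.segmentation_mask <- function(x, ...) {
  cat(sprintf("<segmentation_mask> category %s (%s backend), %d fish-free px\n",
              x$category, x$backend, sum(x$fish_free)))
  invisible(x)
}

#' Classical three-category segmentation of a CFP image
#'
#' Deterministic backend classifying a CFP image as `pattern` (a coherent
#' annular fish distribution with a fish-free zone around the structure),
#' `out_of_range` (no fish anywhere within sonar range) or `invalid`
#' (noisy, no coherent pattern), and extracting the fish-free region:
#'
#' 1. binarise at `echo_threshold` (Otsu by default), ignoring everything
#'    inside the exclusion radius;
#' 2. per bearing, find the nearest above-threshold radius `rho(theta)`
#'    beyond the exclusion zone (`max_range` where the bearing is empty);
#' 3. if the fraction of bearings with an echo is below `coverage_min`,
#'    the school is out of sonar range: the fish-free region is the full
#'    disc of radius `max_range`;
#' 4. smooth `rho` with a circular running median; the fish-free region
#'    is the star-shaped set of pixels closer to the centre than the
#'    smoothed profile at their bearing;
#' 5. if the eroded region (see [seg_params()]) collapses below
#'    `min_region_px` or contains more than `noise_max` above-threshold
#'    pixels, the image is invalid (empty fish-free raster); otherwise it
#'    is a pattern.
#'
#' @param image A `cfp_image`.
#' @param params A [seg_params()].
#' @return A `segmentation_mask`: `category`, logical `fish_free` raster,
#'   the smoothed radius profile `rho_smooth` (m, per bearing), the
#'   threshold used, and the image's geometry/metadata.
#' @export
segment_classical <- function(image, params = seg_params()) {
  stopifnot(inherits(image, "cfp_image"))
  cfg <- image$config
  thr <- params$echo_threshold
  if (is.null(thr)) thr <- annulus_threshold(image)

  polar <- image_to_polar(image, cfg)
  rc <- range_centres(cfg)
  beyond <- rc > cfg$exclusion_radius
  rho <- apply(polar, 1, function(row) {
    k <- which(row > thr & beyond)
    if (length(k)) rc[k[1]] else NA_real_
  })
  coverage <- mean(!is.na(rho))
  r_px <- pixel_radius_m(image)

  if (coverage < params$coverage_min) {
    ff <- r_px <= cfg$max_range
    return(new_segmentation_mask("out_of_range", ff, image, "classical",
                                 list(rho_smooth = rep(cfg$max_range,
                                                       cfg$n_bearings),
                                      threshold = thr,
                                      coverage = coverage)))
  }

  rho[is.na(rho)] <- cfg$max_range
  rho_s <- circular_median(rho, params$smooth_window)
  bb <- pixel_bearing_bin(image)
  ff <- r_px < rho_s[bb] & r_px <= cfg$max_range

  margin <- params$erode_px * image$metres_per_pixel
  eroded <- r_px < (rho_s[bb] - margin) & r_px > cfg$exclusion_radius
  n_eroded <- sum(eroded)
  noise_frac <- if (n_eroded) mean(image$pixels[eroded] > thr) else 1
  if (n_eroded < params$min_region_px || noise_frac > params$noise_max) {
    empty <- matrix(FALSE, nrow(image$pixels), ncol(image$pixels))
    return(new_segmentation_mask("invalid", empty, image, "classical",
                                 list(rho_smooth = rho_s, threshold = thr,
                                      coverage = coverage,
                                      noise_frac = noise_frac)))
  }
  new_segmentation_mask("pattern", ff, image, "classical",
                        list(rho_smooth = rho_s, threshold = thr,
                             coverage = coverage, noise_frac = noise_frac))
}

#' Segment a CFP image with a chosen backend
#'
#' Dispatch wrapper over the deterministic classical backend and the
#' trainable backend (see [train_segmenter()]).
#'
#' @param image A `cfp_image`.
#' @param backend `"classical"` or `"dl"`.
#' @param params A [seg_params()] (classical backend).
#' @param model A trained `segmenter_model` (required for `"dl"`).
#' @return A `segmentation_mask`.
#' @export
segment <- function(image, backend = c("classical", "dl"),
                    params = seg_params(), model = NULL) {
  backend <- match.arg(backend)
  if (backend == "classical") return(segment_classical(image, params))
  if (is.null(model))
    stop("backend 'dl' requires a trained model (see train_segmenter)")
  segment_trained(image, model)
}
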