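#' Trimmed before/during/after phase windows around a stimulus event
#'
#' The first and last `trim` seconds of each phase coincide with
#' transition periods between treatments and are discarded, so a
#' `duration`-second stimulus yields three half-open windows of length
#' `duration - 2 * trim` each (50 s under the default 60 s / 5 s
#' protocol): before ends `trim` seconds ahead of onset, during sits
#' inside the stimulus, and after starts `trim` seconds past the offset.
#'
#' @param onset Stimulus onset (trial seconds).
#' @param duration Stimulus duration (s).
#' @param trim Seconds discarded at each phase boundary (>= 0).
#' @return Data frame with columns `phase` (`before`, `during`, `after`),
#'   `start`, `end`; intervals are half-open `[start, end)`.
#' @export
#' @examples
#' phase_windows(1000)   # [945,995) [1005,1055) [1065,1115)
phase_windows <- function(onset, duration = 60, trim = 5) {
  if (trim < 0) stop("trim must be >= 0")
  if (duration <= 2 * trim)
    stop("duration must exceed twice the trim")
  len <- duration - 2 * trim
  data.frame(
    phase = c("before", "during", "after"),
    start = c(onset - trim - len, onset + trim, onset + duration + trim),
    end = c(onset - trim, onset + duration - trim,
            onset + duration + trim + len),
    stringsAsFactors = FALSE)
}

#' Accumulate sonar revolutions into a Cumulative Fish Presence image
#'
#' Selects the revolutions whose full span `[t_start, t_start +
#' scan_period)` lies inside the window (a partially included revolution
#' would mix bearings from both sides of a treatment transition), renders
#' each to a circular-scan image, and combines them pixelwise.  The
#' default reduction is the maximum — a pixel is bright if a fish was
#' ever detected there during the window — which is what the fish-free
#' region semantics of the segmentation assume; `sum` and `mean` are
#' available for densitometric use.
#'
#' @param frames List of [scan_frame()]s.
#' @param window Numeric length-2 `c(start, end)` or a one-row subset of a
#'   [phase_windows()] frame.
#' @param metres_per_pixel Raster scale (m/px).
#' @param reduce `"max"` (default), `"sum"` or `"mean"`.
#' @param meta Named list of treatment metadata carried on the image
#'   (e.g. `phase`, `level`, `pen`, `depth`, `replicate`).
#' @return A `cfp_image`: fields `pixels`, `centre`, `metres_per_pixel`,
#'   `config`, `window`, `n_frames`, `reduce`, `meta`.
#' @export
accumulate_cfp <- function(frames, window, metres_per_pixel = NULL,
                           reduce = c("max", "sum", "mean"),
                           meta = list()) {
  reduce <- match.arg(reduce)
  if (is.data.frame(window)) {
    if (!is.null(window$phase) && is.null(meta$phase))
      meta$phase <- window$phase[1]
    window <- c(window$start[1], window$end[1])
  }
  stopifnot(length(window) == 2, window[2] > window[1])
  cfg <- frames[[1]]$config
  if (is.null(metres_per_pixel)) metres_per_pixel <- cfg$range_resolution
  t0 <- vapply(frames, function(f) f$t_start, numeric(1))
  sel <- which(t0 >= window[1] & t0 + cfg$scan_period <= window[2])
  if (length(sel) == 0)
    stop(structure(
      class = c("pensonar_empty_window", "error", "condition"),
      list(message = sprintf(
             "no revolution lies fully inside window [%g, %g) (%d frames supplied)",
             window[1], window[2], length(frames)),
           call = sys.call(-1), window = window, n_frames = length(frames))))
  acc <- NULL
  for (i in sel) {
    img <- render_frame(frames[[i]], metres_per_pixel)
    acc <- if (is.null(acc)) img$pixels
           else if (reduce == "max") pmax(acc, img$pixels)
           else acc + img$pixels
  }
  if (reduce == "mean") acc <- acc / length(sel)
  structure(
    list(pixels = acc, centre = img$centre,
         metres_per_pixel = metres_per_pixel, config = cfg,
         window = window, n_frames = length(sel), reduce = reduce,
         meta = meta),
    class = "cfp_image")
}

#' Construct a CFP image directly from a raster
#'
#' For tests and for importing externally built rasters: wraps a square
#' pixel matrix (odd side, `[x, y]` layout, y up) as a `cfp_image`.
#'
#' @param pixels Square numeric matrix with odd side length.
#' @param config A [sonar_config()] describing the polar grid the image
#'   will be analysed on.
#' @param metres_per_pixel Raster scale (m/px).
#' @param meta Named list of metadata.
#' @param n_frames Number of revolutions the raster represents.
#' @return A `cfp_image`.
#' @export
cfp_image <- function(pixels, config, metres_per_pixel, meta = list(),
                      n_frames = 1L) {
  stopifnot(is.matrix(pixels), nrow(pixels) == ncol(pixels),
            nrow(pixels) %% 2L == 1L)
  structure(
    list(pixels = pixels, centre = (nrow(pixels) + 1L) %/% 2L,
         metres_per_pixel = metres_per_pixel, config = config,
         window = c(NA_real_, NA_real_), n_frames = n_frames,
         reduce = "max", meta = meta),
    class = "cfp_image")
}

#' @export
print.cfp_image <- function(x, ...) {
  cat(sprintf("<cfp_image> %dx%d px at %.3f m/px, %d frame(s)%s\n",
              nrow(x$pixels), ncol(x$pixels), x$metres_per_pixel,
              x$n_frames,
              if (!is.null(x$meta$phase)) paste0(", phase ", x$meta$phase)
              else ""))
  invisible(x)
}
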