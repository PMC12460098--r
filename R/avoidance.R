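#' Inner-perimeter contour of the fish-free region
#'
#' Returns the boundary pixels of the fish-free region under the
#' standard 8-connected-region / 4-connected-background convention: the
#' fish-free pixels with at least one 4-neighbour outside the region
#' (pixels beyond the raster edge count as outside).  For an
#' `out_of_range` mask this is the circle at `max_range`.  The pixels
#' are ordered by angle around the centre, which traces the contour for
#' the star-shaped regions the segmentation produces.
#'
#' @param mask A `segmentation_mask` with category `pattern` or
#'   `out_of_range`.
#' @return Integer matrix with columns `x`, `y` (pixel indices).
#' @export
inner_contour <- function(mask) {
  stopifnot(inherits(mask, "segmentation_mask"))
  if (mask$category == "invalid")
    stop(structure(
      class = c("pensonar_not_measurable", "error", "condition"),
      list(message = "invalid-category mask has no measurable contour",
           call = sys.call(-1))))
  reg <- mask$fish_free
  side <- nrow(reg)
  pad <- matrix(FALSE, side + 2L, side + 2L)
  pad[2:(side + 1L), 2:(side + 1L)] <- reg
  interior <- reg
  for (s in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
    interior <- interior &
      pad[(2:(side + 1L)) + s[1], (2:(side + 1L)) + s[2]]
  }
  bnd <- which(reg & !interior, arr.ind = TRUE)
  colnames(bnd) <- c("x", "y")
  ang <- atan2(bnd[, "y"] - mask$centre, bnd[, "x"] - mask$centre)
  bnd[order(ang), , drop = FALSE]
}

#' Avoidance distance of one segmented CFP image
#'
#' The avoidance distance is the mean Euclidean distance from the pixels
#' along the inner perimeter of the fish distribution (the boundary of
#' the fish-free region) to the structure centre, in metres.  Because
#' the centres of the last fish-free pixels lie half a pixel inside the
#' geometric boundary they represent, a constant half-pixel coverage
#' offset is added to the mean contour radius.  For an
#' `out_of_range` image every fish has fled beyond the sonar's reach, so
#' the distance is censored at `max_range` and flagged; an `invalid`
#' image yields no measurement (error).
#'
#' @param mask A `segmentation_mask`.
#' @param metres_per_pixel Raster scale; defaults to the mask's own.
#' @return One-row data frame: `distance_m`, `censored`, `category`,
#'   `n_contour`, plus any `phase`, `level`, `pen`, `depth`, `replicate`
#'   metadata carried on the mask.
#' @export
avoidance_distance <- function(mask, metres_per_pixel = mask$metres_per_pixel) {
  stopifnot(inherits(mask, "segmentation_mask"))
  if (mask$category == "invalid")
    stop(structure(
      class = c("pensonar_not_measurable", "error", "condition"),
      list(message = "invalid-category mask yields no distance",
           call = sys.call(-1))))
  if (mask$category == "out_of_range") {
    d <- mask$config$max_range
    censored <- TRUE
    n_contour <- NA_integer_
  } else {
    ctr <- inner_contour(mask)
    rad <- sqrt((ctr[, "x"] - mask$centre)^2 + (ctr[, "y"] - mask$centre)^2)
    d <- (mean(rad) + 0.5) * metres_per_pixel
    censored <- FALSE
    n_contour <- nrow(ctr)
  }
  out <- data.frame(distance_m = d, censored = censored,
                    category = mask$category, n_contour = n_contour,
                    stringsAsFactors = FALSE)
  for (f in c("phase", "level", "pen", "depth", "replicate"))
    if (!is.null(mask$meta[[f]])) out[[f]] <- mask$meta[[f]]
  out
}
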