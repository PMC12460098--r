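# Image and sidecar output: CFP rasters as 16-bit TIFF, segmentation
# masks as 8-bit PNG, each with a JSON sidecar carrying the metadata the
# raster formats cannot.

# Raster [x, y] (y up) -> display matrix (row 1 = top).
raster_to_display <- function(pixels) t(pixels[, ncol(pixels):1])

#' Write a CFP image as 16-bit TIFF with a JSON sidecar
#'
#' Intensities are scaled by the image maximum to the 16-bit range; the
#' scale factor, window, phase and treatment metadata go to
#' `<path>.json`.
#'
#' @param cfp A `cfp_image`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_cfp <- function(cfp, path) {
  stopifnot(inherits(cfp, "cfp_image"))
  vmax <- max(cfp$pixels, 1e-12)
  tiff::writeTIFF(raster_to_display(cfp$pixels / vmax), path,
                  bits.per.sample = 16)
  side <- list(intensity_scale = vmax,
               metres_per_pixel = cfp$metres_per_pixel,
               window = cfp$window, n_frames = cfp$n_frames,
               reduce = cfp$reduce, meta = cfp$meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' Write a segmentation mask as 8-bit PNG with a JSON sidecar
#'
#' Fish-free pixels are white (255), fish/unknown pixels black (0),
#' matching the white-region / black-mask labelling convention; the
#' category and backend go to `<path>.json`.
#'
#' @param mask A `segmentation_mask`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "segmentation_mask"))
  png::writePNG(raster_to_display(mask$fish_free * 1), path)
  side <- list(category = mask$category, backend = mask$backend,
               metres_per_pixel = mask$metres_per_pixel,
               meta = mask$meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read a mask PNG written by [write_mask()]
#'
#' @param path PNG path (the `<path>.json` sidecar must exist).
#' @param config A [sonar_config()] for the mask geometry.
#' @return A `segmentation_mask`.
#' @export
read_mask <- function(path, config) {
  m <- png::readPNG(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  disp <- m > 0.5
  pixels <- t(disp)[, nrow(disp):1]   # invert raster_to_display
  img <- list(pixels = pixels * 1, centre = (nrow(pixels) + 1L) %/% 2L,
              metres_per_pixel = side$metres_per_pixel, config = config,
              meta = side$meta)
  new_segmentation_mask(side$category, pixels > 0.5, img, side$backend)
}
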