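# Trainable segmentation backend: a single-hidden-layer neural network
# (nnet) classifying each (bearing, range) bin as fish-free or not from
# local and radial-context features, with the category derived from the
# predicted mask by the same rules as the mask invariants.

# Per-bin feature matrix for one CFP image, on the image's polar grid.
# Features are scale-free so the learner transfers across trials:
#  - radius fraction r / max_range
#  - bin intensity / robust image scale
#  - local mean intensity (3 bearings x 5 range bins) / robust scale
#  - prefix maximum intensity at smaller radii on the same bearing
#  - global above-threshold fraction of the annulus (image-level noise)
segmenter_features <- function(image) {
  cfg <- image$config
  polar <- image_to_polar(image, cfg)
  rc <- range_centres(cfg)
  q <- stats::quantile(polar[, rc > cfg$exclusion_radius], 0.99)
  if (q <= 0) q <- 1
  z <- pmin(polar / q, 2)
  nb <- nrow(z); nk <- ncol(z)
  # local mean via separable box filter with circular bearing wrap
  zi <- rbind(z[nb, , drop = FALSE], z, z[1, , drop = FALSE])
  sm_b <- (zi[1:nb, ] + zi[2:(nb + 1), ] + zi[3:(nb + 2), ]) / 3
  zp <- cbind(sm_b[, 1], sm_b[, 1], sm_b, sm_b[, nk], sm_b[, nk])
  loc <- (zp[, 1:nk] + zp[, 2:(nk + 1)] + zp[, 3:(nk + 2)] +
          zp[, 4:(nk + 3)] + zp[, 5:(nk + 4)]) / 5
  pmax_in <- t(apply(z, 1, cummax))
  noise <- mean(z[, rc > cfg$exclusion_radius] > 0.5)
  cbind(radius = rep(rc / cfg$max_range, each = nb),
        inten = as.vector(z), local = as.vector(loc),
        prefix_max = as.vector(pmax_in),
        noise = rep(noise, nb * nk))
}

# Fish-free label of every polar bin, from a mask's raster.
segmenter_labels <- function(mask) {
  ff <- matrix(as.numeric(mask$fish_free), nrow(mask$fish_free))
  img <- list(pixels = ff, centre = mask$centre,
              metres_per_pixel = mask$metres_per_pixel)
  as.vector(image_to_polar(img, mask$config)) > 0.5
}

#' Train the trainable segmentation backend
#'
#' Fits a single-hidden-layer neural network that classifies each
#' (bearing, range) bin of a CFP image as fish-free or fish/noise, from
#' local intensity and radial-context features.  The training set must
#' contain all three categories (`pattern`, `out_of_range`, `invalid`) so
#' the learner sees full-disc, annular and saturated images.  At
#' prediction time the category is derived from the predicted mask: an
#' (almost) full disc of fish-free bins means out of range, a collapsed
#' region means invalid, anything else is a pattern whose fish-free
#' region is rebuilt from the predicted per-bearing boundary.
#'
#' @param dataset List of `list(image = <cfp_image>, mask =
#'   <segmentation_mask>)` training pairs covering all three categories.
#' @param hidden Hidden-layer size.
#' @param n_sample Number of polar bins sampled per image for training.
#' @param maxit nnet iteration budget.
#' @param seed Integer seed (sampling and weight initialisation).
#' @return A `segmenter_model`.
#' @export
train_segmenter <- function(dataset, hidden = 8L, n_sample = 2000L,
                            maxit = 200L, seed = 1) {
  if (length(dataset) == 0) stop("dataset is empty")
  cats <- vapply(dataset, function(d) d$mask$category, character(1))
  missing <- setdiff(c("pattern", "out_of_range", "invalid"), cats)
  if (length(missing))
    stop("dataset lacks categories: ", paste(missing, collapse = ", "))
  set.seed(seed)
  xs <- list(); ys <- list()
  for (d in dataset) {
    X <- segmenter_features(d$image)
    y <- segmenter_labels(d$mask)
    take <- sample(nrow(X), min(n_sample, nrow(X)))
    xs[[length(xs) + 1L]] <- X[take, , drop = FALSE]
    ys[[length(ys) + 1L]] <- y[take]
  }
  X <- do.call(rbind, xs); y <- unlist(ys)
  fit <- nnet::nnet(X, as.numeric(y), size = hidden, decay = 1e-3,
                    maxit = maxit, entropy = TRUE, trace = FALSE)
  structure(list(fit = fit, hidden = hidden), class = "segmenter_model")
}

# Predict with the trainable backend; same output contract as
# segment_classical.
segment_trained <- function(image, model,
                            free_full = 0.97, min_region_px = 50L,
                            smooth_window = 9L) {
  stopifnot(inherits(model, "segmenter_model"))
  cfg <- image$config
  X <- segmenter_features(image)
  p <- as.vector(stats::predict(model$fit, X))
  free <- matrix(p > 0.5, cfg$n_bearings, cfg$n_range_bins)
  rc <- range_centres(cfg)
  beyond <- rc > cfg$exclusion_radius
  frac_free <- mean(free[, beyond])
  r_px <- pixel_radius_m(image)
  if (frac_free >= free_full) {
    ff <- r_px <= cfg$max_range
    return(new_segmentation_mask("out_of_range", ff, image, "dl",
                                 list(frac_free = frac_free)))
  }
  # per bearing: first bin beyond the exclusion zone predicted occupied
  rho <- apply(free, 1, function(row) {
    k <- which(!row & beyond)
    if (length(k)) rc[k[1]] else cfg$max_range
  })
  rho_s <- circular_median(rho, smooth_window)
  bb <- pixel_bearing_bin(image)
  ff <- r_px < rho_s[bb] & r_px <= cfg$max_range
  n_in <- sum(ff & r_px > cfg$exclusion_radius)
  if (n_in < min_region_px) {
    empty <- matrix(FALSE, nrow(image$pixels), ncol(image$pixels))
    return(new_segmentation_mask("invalid", empty, image, "dl",
                                 list(frac_free = frac_free)))
  }
  new_segmentation_mask("pattern", ff, image, "dl",
                        list(rho_smooth = rho_s, frac_free = frac_free))
}
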