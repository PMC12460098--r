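# Shared desk-size geometry and raster builders for the suite.

small_config <- function(...) {
  sonar_config(n_bearings = 120L, n_range_bins = 50L,
               range_resolution = 0.1, scan_period = 5,
               exclusion_radius = 0.5, ...)
}

# Hand-built CFP raster: a clean annulus of given inner radius and
# thickness (in pixels) on a square raster matching `config`'s extent.
annulus_cfp <- function(config, mpp, r_inner_px, thickness_px = 15,
                        value = 1) {
  half <- floor(config$max_range / mpp)
  side <- 2L * half + 1L
  c0 <- half + 1L
  d <- seq_len(side) - c0
  r <- sqrt(outer(d^2, d^2, `+`))
  px <- matrix(0, side, side)
  px[r >= r_inner_px & r <= r_inner_px + thickness_px] <- value
  cfp_image(px, config, mpp)
}

# CFP with an arbitrary star-shaped fish boundary rho_px(theta in
# [0, 2pi)), painted as a band outward of the boundary.
star_cfp <- function(config, mpp, rho_px_fun, thickness_px = 12,
                     value = 1) {
  half <- floor(config$max_range / mpp)
  side <- 2L * half + 1L
  c0 <- half + 1L
  d <- seq_len(side) - c0
  dx <- matrix(d, side, side)
  dy <- matrix(d, side, side, byrow = TRUE)
  r <- sqrt(dx^2 + dy^2)
  ang <- atan2(dy, dx) %% (2 * pi)
  rho <- rho_px_fun(ang)
  px <- matrix(0, side, side)
  px[r >= rho & r <= rho + thickness_px & r <= half] <- value
  cfp_image(px, config, mpp)
}

# One CFP image of a given category from the generator, at desk scale.
gen_cfp <- function(category, seed, config = small_config()) {
  set.seed(seed)
  sch <- make_schedule("s", 1, duration = 30, break_duration = 40,
                       order = "sequential")
  if (category == "pattern") {
    r0 <- stats::runif(1, 1.2, 3.0)
    p <- school_params(n_agents = 60L, baseline_radius = r0,
                       radial_spread = 0.3, displacement_factor = 0)
    sim <- simulate_frames(p, sch, config, seed = seed, t_end = 60)
    accumulate_cfp(sim$frames, c(0, 25))
  } else if (category == "out_of_range") {
    p <- school_params(n_agents = 0L, baseline_radius = 1.5)
    sim <- simulate_frames(p, sch, config, seed = seed, t_end = 60)
    accumulate_cfp(sim$frames, c(0, 25))
  } else {
    accumulate_cfp(make_invalid_frames(config, burst_level = 5,
                                       n_frames = 5, seed = seed),
                   c(0, 25))
  }
}

# Brute-force boundary oracle: fish-free pixels with at least one
# 4-neighbour (or raster edge) outside the region.
boundary_oracle <- function(region) {
  side <- nrow(region)
  out <- matrix(FALSE, side, side)
  steps <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  for (i in seq_len(side)) for (j in seq_len(side)) {
    if (!region[i, j]) next
    for (s in steps) {
      ii <- i + s[1]; jj <- j + s[2]
      if (ii < 1 || ii > side || jj < 1 || jj > side || !region[ii, jj]) {
        out[i, j] <- TRUE
      }
    }
  }
  which(out, arr.ind = TRUE)
}

# Mean per-replicate percent increase (during vs before) of the
# pipeline-estimated avoidance distance for one displacement factor.
effect_recovery_pct <- function(delta, seed, n_rep = 3,
                                config = sonar_config()) {
  sch <- make_schedule("400Hz", n_rep, seed = seed)
  p <- school_params(displacement_factor = delta)
  sim <- simulate_frames(p, sch, config, seed = seed)
  pct <- vapply(seq_len(nrow(sch)), function(i) {
    w <- phase_windows(sch$onset[i])
    d_b <- avoidance_distance(
      segment_classical(accumulate_cfp(sim$frames, w[1, ])))$distance_m
    d_d <- avoidance_distance(
      segment_classical(accumulate_cfp(sim$frames, w[2, ])))$distance_m
    100 * (d_d - d_b) / d_b
  }, numeric(1))
  mean(pct)
}
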