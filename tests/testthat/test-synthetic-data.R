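test_that("schedules follow the stimulus/break protocol", {
  sch <- make_schedule(paste0(c(100, 200, 400, 600, 1000), "Hz"),
                       repetitions = 3, seed = 1)
  expect_equal(nrow(sch), 15L)
  expect_true(all(table(sch$level) == 3L))
  expect_equal(unique(diff(sch$onset)), 660)
  # single event at the configured start time
  one <- make_schedule("a", 1, t_first = 120)
  expect_equal(nrow(one), 1L)
  expect_equal(one$onset, 120)
  expect_error(make_schedule(character(0), 3), "non-empty")
})

test_that("random order is a seeded shuffle of the same event multiset", {
  s1 <- make_schedule(c("a", "b", "c"), 4, seed = 1)
  s2 <- make_schedule(c("a", "b", "c"), 4, seed = 2)
  expect_equal(sort(s1$level), sort(s2$level))
  expect_equal(s1$onset, s2$onset)          # identical onset grid
  expect_equal(s1, make_schedule(c("a", "b", "c"), 4, seed = 1))
})

test_that("ground-truth radius follows exponential response and recovery", {
  sch <- make_schedule("s", 1, seed = 1)
  onset <- sch$onset[1]
  p <- school_params(baseline_radius = 2, displacement_factor = 0.28,
                     relaxation_tau = 1)
  expect_equal(school_radius(p, onset - 1, sch), 2)
  # closed form: r0 + (r0*delta) * (1 - exp(-10))
  expect_equal(school_radius(p, onset + 10, sch),
               2 + 0.56 * (1 - exp(-10)))
  expect_lt(abs(school_radius(p, onset + 10, sch) - 2 * 1.28),
            0.001 * 2 * 1.28)
  # null treatment never moves
  p0 <- school_params(displacement_factor = 0)
  tt <- seq(0, 800, by = 7)
  expect_true(all(school_radius(p0, tt, sch) == p0$baseline_radius))
  # fully recovered well after offset
  expect_equal(school_radius(p, onset + 60 + 5 + 1, sch), 2)
})

test_that("an empty pen yields background noise and structure ring only", {
  cfg <- small_config()
  sch <- make_schedule("s", 1, duration = 30, break_duration = 40,
                       order = "sequential")
  sim <- simulate_frames(school_params(n_agents = 0L), sch, cfg,
                         seed = 3, t_end = 20)
  fr <- sim$frames[[1]]
  rc <- (seq_len(cfg$n_range_bins) - 0.5) * cfg$range_resolution
  beyond <- rc > cfg$exclusion_radius
  # nothing beyond the exclusion radius rises above background scale
  expect_lt(max(fr$intensities[, beyond]), 0.5)
  # the structure ring inside the exclusion zone is bright
  expect_gt(max(fr$intensities[, !beyond]), 2)
})

test_that("pre-stimulus echo ranges match the half-normal sampling model", {
  cfg <- sonar_config()
  sch <- make_schedule("s", 1, seed = 1)
  p <- school_params()     # r0 = 2, spread sd 0.5
  sim <- simulate_frames(p, sch, cfg, seed = 7, t_end = 120)
  rc <- (seq_len(cfg$n_range_bins) - 0.5) * cfg$range_resolution
  beyond <- rc > cfg$exclusion_radius
  ranges <- unlist(lapply(sim$frames, function(fr) {
    hit <- which(fr$intensities > 0.5, arr.ind = TRUE)
    hit <- hit[rc[hit[, 2]] > cfg$exclusion_radius, , drop = FALSE]
    rc[hit[, 2]]
  }))
  expected <- p$baseline_radius + p$radial_spread * sqrt(2 / pi)
  expect_lt(abs(mean(ranges) - expected) / expected, 0.10)
})

test_that("flight beyond sonar range empties the during-phase frames", {
  cfg <- small_config()      # max_range 5 m
  sch <- make_schedule("s", 1, duration = 30, break_duration = 40,
                       order = "sequential")
  p <- school_params(n_agents = 40L, baseline_radius = 2,
                     displacement_factor = 2.0, radial_spread = 0.2,
                     relaxation_tau = 0.5, out_of_range_flag = TRUE)
  # without the flag the same parameters are rejected
  expect_error(simulate_frames(school_params(
    n_agents = 40L, baseline_radius = 2, displacement_factor = 2.0),
    sch, cfg, seed = 1), "out_of_range_flag")
  sim <- simulate_frames(p, sch, cfg, seed = 9)
  rc <- (seq_len(cfg$n_range_bins) - 0.5) * cfg$range_resolution
  beyond <- rc > cfg$exclusion_radius
  onset <- sch$onset[1]
  during <- Filter(function(f) f$t_start >= onset + 5 &&
                     f$t_start + cfg$scan_period <= onset + 25, sim$frames)
  empty <- vapply(during, function(f)
    sum(f$intensities[, beyond] > 0.5) == 0, logical(1))
  expect_gte(mean(empty), 0.95)
})

test_that("identical seeds give bit-identical frame streams", {
  cfg <- small_config()
  sch <- make_schedule("s", 1, duration = 30, break_duration = 40,
                       order = "sequential")
  p <- school_params(n_agents = 30L, baseline_radius = 1.5)
  a <- simulate_frames(p, sch, cfg, seed = 5, t_end = 30)
  b <- simulate_frames(p, sch, cfg, seed = 5, t_end = 30)
  expect_identical(a, b)
  c <- simulate_frames(p, sch, cfg, seed = 6, t_end = 30)
  expect_false(identical(a$frames, c$frames))
})

test_that("displaced ground truth exceeds baseline during exposure", {
  sch <- make_schedule("s", 2, seed = 1)
  p <- school_params(displacement_factor = 0.28)
  cfg <- sonar_config()
  sim <- simulate_frames(p, sch, cfg, seed = 2)
  tr <- sim$truth
  expect_gt(mean(tr$true_radius_m[tr$phase %in% "during"]),
            mean(tr$true_radius_m[tr$phase %in% "before"]))
  expect_equal(mean(tr$true_radius_m[tr$phase %in% "before"]),
               p$baseline_radius)
})

test_that("frame count per phase window is floor(window / period) +- 1", {
  cfg <- sonar_config()
  sch <- make_schedule("s", 3, seed = 1)
  sim <- simulate_frames(school_params(n_agents = 5L), sch, cfg, seed = 1)
  t0 <- vapply(sim$frames, function(f) f$t_start, numeric(1))
  for (i in 1:3) {
    w <- phase_windows(sch$onset[i])
    for (r in seq_len(nrow(w))) {
      n <- sum(t0 >= w$start[r] & t0 + cfg$scan_period <= w$end[r])
      expect_lte(abs(n - floor(50 / cfg$scan_period)), 1)
    }
  }
})

test_that("invalid frames are saturated, seed-dependent, level-scaled", {
  cfg <- small_config()
  a <- make_invalid_frames(cfg, burst_level = 5, n_frames = 2, seed = 1)
  b <- make_invalid_frames(cfg, burst_level = 5, n_frames = 2, seed = 2)
  expect_false(identical(a[[1]]$intensities, b[[1]]$intensities))
  m_a <- mean(a[[1]]$intensities); m_b <- mean(b[[1]]$intensities)
  expect_lt(abs(m_a - m_b) / m_a, 0.05)
  # burst level 0 reduces to background-only frames
  bg <- make_invalid_frames(cfg, burst_level = 0, n_frames = 1, seed = 1)
  expect_lt(mean(bg[[1]]$intensities), 0.1)
})
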