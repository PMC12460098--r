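#' Build a stimulus treatment schedule
#'
#' Lays out repeated stimulus events (e.g. tones at a set of frequencies,
#' or light levels) on a trial clock: each event lasts `duration` seconds
#' and consecutive events are separated by a `break_duration` pause, so
#' consecutive onsets sit `duration + break_duration` apart.  The default
#' protocol is a 60 s stimulus with a 10 min break.  With
#' `order = "random"` the multiset of level repetitions is shuffled
#' (seeded); with `"sequential"` levels run in blocks in the given order.
#'
#' @param levels Character vector of treatment level labels (non-empty).
#' @param repetitions Number of events per level (>= 1).
#' @param duration Stimulus duration in seconds.
#' @param break_duration Pause between consecutive stimuli in seconds.
#' @param order `"random"` or `"sequential"`.
#' @param seed Optional integer seed for the random order.
#' @param t_first Onset of the first event (seconds); defaults to
#'   `break_duration` so a full pre-stimulus window exists.
#' @return A `treatment_schedule`: data frame with columns `level`,
#'   `onset`, `duration` and one row per event, plus attributes
#'   `break_duration` and `repetitions`.
#' @export
#' @examples
#' sch <- make_schedule(c("100Hz", "400Hz"), repetitions = 3, seed = 1)
#' diff(sch$onset)   # all 660 s under the default protocol
make_schedule <- function(levels, repetitions, duration = 60,
                          break_duration = 600,
                          order = c("random", "sequential"),
                          seed = NULL, t_first = break_duration) {
  if (length(levels) == 0) stop("levels must be non-empty")
  if (repetitions < 1) stop("repetitions must be >= 1")
  if (duration <= 0 || break_duration <= 0)
    stop("duration and break_duration must be > 0")
  order <- match.arg(order)
  labs <- rep(as.character(levels), each = repetitions)
  if (order == "random") {
    if (!is.null(seed)) set.seed(seed)
    labs <- sample(labs)
  }
  n <- length(labs)
  events <- data.frame(
    level = labs,
    onset = t_first + (seq_len(n) - 1) * (duration + break_duration),
    duration = duration,
    stringsAsFactors = FALSE)
  structure(events, class = c("treatment_schedule", "data.frame"),
            break_duration = break_duration, repetitions = repetitions)
}

#' Fish-school behaviour parameters
#'
#' Parameterises the agent-based school used to generate synthetic sonar
#' streams.  The school sits as a noisy annulus around the centred
#' structure: each agent's radial position is the ground-truth inner
#' radius plus a half-normal outward offset, so the annulus has a crisp
#' inner edge at `baseline_radius` (before exposure).  During exposure the
#' inner radius relaxes exponentially toward
#' `baseline_radius * (1 + displacement_factor)` with time constant
#' `relaxation_tau`, and decays back after the stimulus ends; negative
#' displacement factors model attraction toward the source.
#'
#' @param n_agents Number of fish agents painted per revolution.
#' @param baseline_radius Ground-truth inner avoidance radius r0 (m).
#' @param radial_spread Half-normal sd of the outward radial offsets (m).
#' @param displacement_factor Dimensionless displacement delta: during-
#'   exposure target radius is `r0 * (1 + delta)`.  Either a single value
#'   applied to every treatment level or a named vector keyed by level
#'   label (unnamed levels get 0).
#' @param relaxation_tau Response/recovery time constant (s).
#' @param swim_angular_speed Common angular drift of the school (rad/s).
#' @param echo_amplitude Mean echo blob peak intensity.
#' @param speckle_cv Coefficient of variation of the lognormal
#'   multiplicative speckle applied per agent echo.
#' @param background_noise_level Mean of the exponential additive
#'   background noise, on the echo intensity scale.
#' @param out_of_range_flag Allow the during-exposure radius to exceed the
#'   sonar's maximum range (flight beyond sonar range).
#' @return An object of class `school_params`.
#' @export
school_params <- function(n_agents = 150L, baseline_radius = 2.0,
                          radial_spread = 0.5, displacement_factor = 0,
                          relaxation_tau = 1, swim_angular_speed = 0.1,
                          echo_amplitude = 1, speckle_cv = 0.3,
                          background_noise_level = 0.02,
                          out_of_range_flag = FALSE) {
  if (n_agents < 0) stop("n_agents must be >= 0")
  if (radial_spread < 0) stop("radial_spread must be >= 0")
  if (any(1 + displacement_factor <= 0))
    stop("1 + displacement_factor must be > 0")
  if (relaxation_tau <= 0) stop("relaxation_tau must be > 0")
  structure(
    list(n_agents = as.integer(n_agents), baseline_radius = baseline_radius,
         radial_spread = radial_spread,
         displacement_factor = displacement_factor,
         relaxation_tau = relaxation_tau,
         swim_angular_speed = swim_angular_speed,
         echo_amplitude = echo_amplitude, speckle_cv = speckle_cv,
         background_noise_level = background_noise_level,
         out_of_range_flag = out_of_range_flag),
    class = "school_params")
}

# Displacement factor for a given level label.
delta_for_level <- function(params, level) {
  d <- params$displacement_factor
  if (is.null(names(d))) return(d[1])
  if (level %in% names(d)) unname(d[level]) else 0
}

#' Ground-truth inner school radius at time t
#'
#' First-order response-and-recovery dynamics: the inner radius is
#' `baseline_radius` (r0) outside stimulation, rises exponentially toward
#' `r0 * (1 + delta)` with time constant `relaxation_tau` after each
#' stimulus onset, and decays back toward r0 with the same constant after
#' the offset.  More than five time constants after the offset the radius
#' is exactly r0 again (the residual transient, < 1%, is truncated so the
#' after-phase truly represents full recovery).
#'
#' @param params A [school_params()].
#' @param t Time(s) on the trial clock (s); vectorised.
#' @param schedule A [make_schedule()] result.
#' @return Numeric vector of inner radii (m), same length as `t`.
#' @export
school_radius <- function(params, t, schedule) {
  r0 <- params$baseline_radius
  tau <- params$relaxation_tau
  r <- rep(r0, length(t))
  for (i in seq_len(nrow(schedule))) {
    onset <- schedule$onset[i]
    offset <- onset + schedule$duration[i]
    delta <- delta_for_level(params, schedule$level[i])
    if (delta == 0) next
    target <- r0 * (1 + delta)
    during <- t >= onset & t < offset
    r[during] <- r0 + (target - r0) * (1 - exp(-(t[during] - onset) / tau))
    r_off <- r0 + (target - r0) * (1 - exp(-(offset - onset) / tau))
    post <- t >= offset & t < offset + 5 * tau
    r[post] <- r0 + (r_off - r0) * exp(-(t[post] - offset) / tau)
  }
  r
}

# Phase label of time t under the trimmed window convention, or NA when t
# falls in a transition/break period.
phase_at <- function(t, schedule, trim = 5) {
  out <- rep(NA_character_, length(t))
  rep_counter <- stats::setNames(rep(0L, length(unique(schedule$level))),
                                 unique(schedule$level))
  repl <- rep(NA_integer_, length(t))
  lev <- rep(NA_character_, length(t))
  for (i in seq_len(nrow(schedule))) {
    w <- phase_windows(schedule$onset[i], schedule$duration[i], trim)
    rep_counter[schedule$level[i]] <- rep_counter[schedule$level[i]] + 1L
    for (p in seq_len(nrow(w))) {
      sel <- t >= w$start[p] & t < w$end[p]
      out[sel] <- w$phase[p]
      repl[sel] <- rep_counter[schedule$level[i]]
      lev[sel] <- schedule$level[i]
    }
  }
  data.frame(phase = out, level = lev, replicate = repl,
             stringsAsFactors = FALSE)
}

#' Simulate a stream of sonar revolutions for one trial
#'
#' Agents hold angular stations that drift at `swim_angular_speed` and
#' draw, at every revolution, a radial position `r(t) + |N(0, spread)|`
#' where `r(t)` is the ground-truth inner radius under the schedule.  Each
#' visible agent paints a small Gaussian echo blob (sd 2 range bins by 1
#' bearing bin) scaled by lognormal speckle; exponential background noise
#' is added everywhere and a bright ring inside the exclusion zone
#' emulates the structure's self-echo.  Agents beyond `max_range` are not
#' painted (out-of-sonar-range flight).
#'
#' @param params A [school_params()].
#' @param schedule A [make_schedule()] result.
#' @param config A [sonar_config()].
#' @param seed Integer seed; the stream is bit-identical for a fixed seed.
#' @param t_end End of simulation (s); defaults to 120 s after the last
#'   stimulus offset, covering the trimmed after-window.
#' @return A list with `frames` (list of [scan_frame()]s, one per
#'   revolution) and `truth` (data frame: `t`, `true_radius_m`, `phase`,
#'   `level`, `replicate`).
#' @export
simulate_frames <- function(params, schedule, config, seed = 1,
                            t_end = NULL) {
  stopifnot(inherits(params, "school_params"),
            inherits(schedule, "treatment_schedule"),
            inherits(config, "sonar_config"))
  if (params$baseline_radius <= config$exclusion_radius)
    stop("baseline_radius must exceed the exclusion radius")
  dmax <- max(vapply(schedule$level, function(l) delta_for_level(params, l),
                     numeric(1)))
  if (!params$out_of_range_flag &&
      params$baseline_radius * (1 + dmax) > config$max_range)
    stop("displaced radius exceeds max_range; set out_of_range_flag to allow flight beyond sonar range")
  if (is.null(t_end))
    t_end <- max(schedule$onset + schedule$duration) + 120
  set.seed(seed)
  P <- config$scan_period
  t_starts <- seq(0, t_end - P, by = P)
  ang0 <- stats::runif(params$n_agents, 0, 2 * pi)

  # blob footprint in (bearing, range) bin offsets
  db <- -2:2; dk <- -4:4
  blob <- exp(-outer(db^2 / 2, dk^2 / 8, `+`))  # sd: 1 bearing x 2 range bins
  sdlog <- sqrt(log(1 + params$speckle_cv^2))

  # structure self-echo: ring just inside the exclusion zone
  rc <- range_centres(config)
  ring_bins <- which(rc > 0.55 * config$exclusion_radius &
                     rc < 0.85 * config$exclusion_radius)

  nb <- config$n_bearings; nk <- config$n_range_bins
  frames <- vector("list", length(t_starts))
  truth_r <- numeric(length(t_starts))
  for (f in seq_along(t_starts)) {
    t_mid <- t_starts[f] + P / 2
    r_true <- school_radius(params, t_mid, schedule)
    truth_r[f] <- r_true
    inten <- matrix(stats::rexp(nb * nk,
                                rate = 1 / params$background_noise_level),
                    nb, nk)
    if (length(ring_bins))
      inten[, ring_bins] <- inten[, ring_bins] + 3 * params$echo_amplitude
    if (params$n_agents > 0) {
      ang <- (ang0 + params$swim_angular_speed * t_mid) %% (2 * pi)
      rad <- r_true + abs(stats::rnorm(params$n_agents, 0,
                                       params$radial_spread))
      amp <- params$echo_amplitude *
        stats::rlnorm(params$n_agents, -sdlog^2 / 2, sdlog)
      bbin <- (round(ang / (2 * pi) * nb)) %% nb + 1L
      kbin <- floor(rad / config$range_resolution) + 1L
      keep <- which(kbin <= nk)
      for (a in keep) {
        bi <- (bbin[a] + db - 1L) %% nb + 1L
        ki <- kbin[a] + dk
        ok <- ki >= 1L & ki <= nk
        inten[bi, ki[ok]] <- inten[bi, ki[ok]] + amp[a] * blob[, ok]
      }
    }
    frames[[f]] <- scan_frame(config, inten, t_start = t_starts[f])
  }
  ph <- phase_at(t_starts + P / 2, schedule)
  truth <- data.frame(t = t_starts + P / 2, true_radius_m = truth_r,
                      phase = ph$phase, level = ph$level,
                      replicate = ph$replicate, stringsAsFactors = FALSE)
  list(frames = frames, truth = truth)
}

#' Generate saturated-noise (invalid) sonar frames
#'
#' Emulates recordings where no annular fish structure exists: every
#' (bearing, range) bin receives high-intensity broadband noise (an
#' exponential draw with mean `burst_level`) on top of the usual
#' background, so segmentation should label the result invalid.  With
#' `burst_level = 0` the frames reduce to background noise only.
#'
#' @param config A [sonar_config()].
#' @param burst_level Mean burst intensity; should well exceed the echo
#'   amplitude of genuine fish for a convincing invalid frame.
#' @param n_frames Number of revolutions to generate.
#' @param seed Integer seed.
#' @param t_start Trial-clock time of the first revolution.
#' @param background_noise_level Mean of the ever-present background.
#' @return List of [scan_frame()]s.
#' @export
make_invalid_frames <- function(config, burst_level, n_frames = 1L,
                                seed = 1, t_start = 0,
                                background_noise_level = 0.02) {
  stopifnot(inherits(config, "sonar_config"))
  if (burst_level < 0) stop("burst_level must be >= 0")
  set.seed(seed)
  nb <- config$n_bearings; nk <- config$n_range_bins
  lapply(seq_len(n_frames), function(f) {
    inten <- matrix(stats::rexp(nb * nk, rate = 1 / background_noise_level),
                    nb, nk)
    if (burst_level > 0)
      inten <- inten + matrix(stats::rexp(nb * nk, rate = 1 / burst_level),
                              nb, nk)
    scan_frame(config, inten,
               t_start = t_start + (f - 1L) * config$scan_period)
  })
}
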