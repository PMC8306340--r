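#' Configuration for the synthetic monolayer movie generator
#'
#' Describes a paced (or spontaneously beating) monolayer imaged with a
#' mapping camera: grid geometry, acquisition timing, pacing schedule, a
#' planar (or point-source) wave, per-pixel kinetic heterogeneity,
#' photobleaching drift and additive shot-like noise. Every simulated
#' quantity has an analytic ground truth, returned alongside the movie by
#' [simulate_movie()].
#'
#' @param template An [ap_template()] or [ca_template()] describing the
#'   per-pixel transient.
#' @param rows,cols Camera grid size (default 100 x 100).
#' @param frame_interval Frame interval, ms (default 2 ms, i.e. 500 Hz).
#' @param pixel_pitch Pixel pitch, mm (default 0.1 mm).
#' @param cycle_length Pacing cycle length, ms.
#' @param n_beats Number of paced beats.
#' @param first_stimulus Time of the first stimulus, ms. The lead-in before
#'   it samples the true diastolic resting level.
#' @param planar_wave_speed Wave speed, mm/ms.
#' @param wave_origin One of `"left"`, `"right"`, `"top"`, `"bottom"`,
#'   `"point"`.
#' @param point_origin `(row, col)` of the point source when
#'   `wave_origin = "point"`.
#' @param pixel_heterogeneity Lognormal sigma applied multiplicatively to the
#'   per-pixel upstroke duration (AP) or time to peak (Ca).
#' @param duration_heterogeneity Lognormal sigma applied multiplicatively to
#'   the per-pixel APD30/APD80 (AP) or decay tau (Ca).
#' @param noise_sd Additive white Gaussian noise, as a fraction of the
#'   signal amplitude.
#' @param baseline_offset Diastolic baseline, camera counts.
#' @param amplitude_counts Signal amplitude, camera counts.
#' @param bleach Photobleaching drift parameters, a list
#'   `list(b0, b1, b2, tau)` for `b0 + b1 t + b2 exp(-t / tau)` counts.
#' @param tissue_margin Width (pixels) of a signal-free border emulating
#'   pixels outside the monolayer.
#' @param spontaneous_period If non-NULL, ms between spontaneous beats; the
#'   movie is unpaced and `duration` must be given.
#' @param duration Movie duration, ms (computed from the pacing schedule if
#'   NULL).
#' @param digitize Round to integer counts and clamp to the 16-bit camera
#'   range.
#' @param seed Integer seed; fixing it makes every output reproducible.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(template,
                       rows = 100, cols = 100,
                       frame_interval = 2, pixel_pitch = 0.1,
                       cycle_length = 1000, n_beats = 3,
                       first_stimulus = 100,
                       planar_wave_speed = 0.2,
                       wave_origin = c("left", "right", "top", "bottom", "point"),
                       point_origin = NULL,
                       pixel_heterogeneity = 0,
                       duration_heterogeneity = 0,
                       noise_sd = 0,
                       baseline_offset = 1000,
                       amplitude_counts = 2000,
                       bleach = list(b0 = 0, b1 = 0, b2 = 0, tau = 5000),
                       tissue_margin = 0,
                       spontaneous_period = NULL,
                       duration = NULL,
                       digitize = FALSE,
                       seed = NULL) {
  wave_origin <- match.arg(wave_origin)
  stopifnot(inherits(template, "map_template"),
            rows >= 1, cols >= 1, frame_interval > 0, pixel_pitch > 0,
            planar_wave_speed > 0, pixel_heterogeneity >= 0,
            duration_heterogeneity >= 0, noise_sd >= 0)
  if (wave_origin == "point" && is.null(point_origin))
    stop("point_origin must be given for a point-source wave")
  if (is.null(spontaneous_period)) {
    stopifnot(cycle_length > 0, n_beats >= 1)
    if (is.null(duration)) duration <- first_stimulus + n_beats * cycle_length
  } else {
    stopifnot(spontaneous_period > 0)
    if (is.null(duration))
      stop("duration must be given for a spontaneous recording")
  }
  b <- utils::modifyList(list(b0 = 0, b1 = 0, b2 = 0, tau = 5000), bleach)
  structure(
    list(template = template, rows = rows, cols = cols,
         frame_interval = frame_interval, pixel_pitch = pixel_pitch,
         cycle_length = cycle_length, n_beats = n_beats,
         first_stimulus = first_stimulus,
         planar_wave_speed = planar_wave_speed, wave_origin = wave_origin,
         point_origin = point_origin,
         pixel_heterogeneity = pixel_heterogeneity,
         duration_heterogeneity = duration_heterogeneity,
         noise_sd = noise_sd, baseline_offset = baseline_offset,
         amplitude_counts = amplitude_counts, bleach = b,
         tissue_margin = tissue_margin,
         spontaneous_period = spontaneous_period, duration = duration,
         digitize = digitize, seed = seed),
    class = "sim_config")
}

#' Lognormal sigma inducing a target upstroke-velocity RSD
#'
#' With per-pixel upstroke durations `u = u0 * exp(N(0, sigma^2))`, the
#' per-pixel upstroke velocity `1/u` is lognormal and its relative standard
#' deviation is `sqrt(exp(sigma^2) - 1)`. Inverting gives the sigma that
#' produces a requested velocity RSD.
#'
#' @param rsd Target relative standard deviation of upstroke velocity.
#' @return Lognormal sigma for `pixel_heterogeneity`.
#' @export
upstroke_sigma_for_rsd <- function(rsd) {
  stopifnot(rsd >= 0)
  sqrt(log(1 + rsd^2))
}

activation_offsets <- function(config) {
  r <- matrix(seq_len(config$rows), config$rows, config$cols)
  c_ <- matrix(seq_len(config$cols), config$rows, config$cols, byrow = TRUE)
  d <- switch(config$wave_origin,
    left = (c_ - 1) * config$pixel_pitch,
    right = (config$cols - c_) * config$pixel_pitch,
    top = (r - 1) * config$pixel_pitch,
    bottom = (config$rows - r) * config$pixel_pitch,
    point = sqrt((r - config$point_origin[1])^2 +
                 (c_ - config$point_origin[2])^2) * config$pixel_pitch)
  d / config$planar_wave_speed
}

#' Simulate a mapping movie with analytic ground truth
#'
#' Builds per-pixel traces as `baseline + amplitude * template(t -
#' activation; pixel parameters) + drift + noise`, where the activation time
#' of each pixel is the stimulus time plus its wavefront travel time.
#' Successive beats superpose additively, so an incompletely decayed calcium
#' tail carries into the next diastole exactly as in a real recording.
#'
#' @param config A [sim_config()].
#' @return A list with elements `movie` (a [mapping_movie()]) and `truth`
#'   (class `ground_truth`): per-pixel activation offsets (ms after the
#'   stimulus), the per-pixel kinetic parameters actually drawn, the tissue
#'   mask, `true_cv` (mm/ms, equal to `planar_wave_speed`) and
#'   `true_upstroke_rsd` computed from the drawn per-pixel values.
#' @export
simulate_movie <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  F_ <- floor(config$duration / config$frame_interval) + 1L
  t <- (seq_len(F_) - 1L) * config$frame_interval
  P <- config$rows * config$cols
  off <- activation_offsets(config)          # rows x cols, ms after stimulus
  max_off <- max(off)

  if (is.null(config$spontaneous_period)) {
    beat_times <- config$first_stimulus +
      (seq_len(config$n_beats) - 1L) * config$cycle_length
    stim <- beat_times
    if (max(beat_times) + max_off > config$duration)
      stop("movie too short for the configured beats")
  } else {
    k <- 0:floor((config$duration - config$first_stimulus) /
                 config$spontaneous_period)
    beat_times <- config$first_stimulus + k * config$spontaneous_period
    beat_times <- beat_times[beat_times + max_off <= config$duration]
    stim <- numeric(0)
    if (length(beat_times) < 1L)
      stop("movie too short for the configured beats")
  }

  tissue <- matrix(TRUE, config$rows, config$cols)
  m <- config$tissue_margin
  if (m > 0) {
    tissue[] <- FALSE
    tissue[(m + 1):(config$rows - m), (m + 1):(config$cols - m)] <- TRUE
  }

  is_ap <- inherits(config$template, "ap_template")
  u0 <- if (is_ap) config$template$upstroke_duration else config$template$time_to_peak
  u_pix <- if (config$pixel_heterogeneity > 0)
    u0 * exp(stats::rnorm(P, 0, config$pixel_heterogeneity)) else rep(u0, P)
  s_pix <- if (config$duration_heterogeneity > 0)
    exp(stats::rnorm(P, 0, config$duration_heterogeneity)) else rep(1, P)
  if (is_ap && any(u_pix >= config$template$apd30 * s_pix))
    stop("heterogeneity draw produced upstroke_duration >= apd30; reduce sigma")

  span <- if (is_ap) {
    1.15 * config$template$apd80 * max(s_pix)
  } else {
    template_span(config$template) * max(s_pix) + max(u_pix) - u0
  }

  M <- matrix(0, F_, P)
  offv <- as.numeric(off)
  for (s_k in beat_times) {
    fi <- which(t >= s_k & t <= s_k + max_off + span)
    if (!length(fi)) next
    tt <- outer(t[fi], s_k + offv, "-")
    nf <- length(fi)
    v <- template_value(config$template, tt,
                        upstroke = rep(u_pix, each = nf),
                        scale = rep(s_pix, each = nf))
    dim(v) <- c(nf, P)
    M[fi, ] <- M[fi, ] + v
  }
  M <- M * (config$amplitude_counts * rep(as.numeric(tissue), each = F_))
  drift <- config$baseline_offset + config$bleach$b0 + config$bleach$b1 * t +
    config$bleach$b2 * exp(-t / config$bleach$tau)
  M <- M + drift
  if (config$noise_sd > 0)
    M <- M + stats::rnorm(length(M), 0, config$noise_sd * config$amplitude_counts)
  if (config$digitize) M <- pmin(pmax(round(M), 0), 65535)

  movie <- mapping_movie(
    array(M, c(F_, config$rows, config$cols)),
    frame_interval = config$frame_interval, pixel_pitch = config$pixel_pitch,
    stimulus_times = stim,
    cycle_length = if (is.null(config$spontaneous_period)) config$cycle_length else NA_real_,
    channel = if (is_ap) "voltage" else "calcium")

  vel <- 1 / u_pix[as.numeric(tissue) > 0]
  truth <- structure(list(
    activation_offset = off,
    mask = tissue,
    true_cv = config$planar_wave_speed,
    true_upstroke_rsd = stats::sd(vel) / mean(vel),
    beat_times = beat_times,
    upstroke_duration = matrix(u_pix, config$rows, config$cols),
    apd30 = if (is_ap) matrix(config$template$apd30 * s_pix, config$rows, config$cols),
    apd80 = if (is_ap) matrix(config$template$apd80 * s_pix, config$rows, config$cols),
    time_to_peak = if (!is_ap) matrix(u_pix, config$rows, config$cols),
    decay_tau = if (!is_ap) matrix(config$template$decay_tau * s_pix,
                                   config$rows, config$cols)),
    class = "ground_truth")
  list(movie = movie, truth = truth)
}
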