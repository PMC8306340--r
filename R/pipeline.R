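#' End-to-end voltage-mapping analysis
#'
#' Runs the full chain on a paced voltage movie: beat segmentation,
#' photobleaching correction, SNR masking, optional masked spatial
#' smoothing, per-beat normalization, per-pixel AP metrics, and the
#' conduction-velocity field from the beat-averaged activation map.
#' Spatial smoothing is off by default because it mixes neighboring
#' pixels' kinetics and therefore biases the spatial-heterogeneity (RSD)
#' metrics downward; enable it for visually cleaner maps only.
#'
#' @param movie A paced voltage [mapping_movie()].
#' @param snr_threshold SNR mask threshold.
#' @param kernel_size Spatial smoothing kernel (1 = off).
#' @param baseline_method Drift model for [remove_baseline()].
#' @param pre_roll,discard_first,artifact_guard Beat handling, see
#'   [segment_beats()] and [normalize_beats()].
#' @param cv_radius,cv_residual_threshold Conduction fit settings, see
#'   [local_velocity()].
#' @param apd_ref APD reference convention, see [apd()].
#' @return A list of class `vm_analysis`: `apmap`, `field`, `mask`,
#'   `windows`, and `summary` (APD30/APD80 means and SDs, upstroke mean
#'   and RSD, `cv_mean_cm_s`, `cv_rsd`, `n_valid_pixels`).
#' @export
analyze_vm <- function(movie, snr_threshold = 3, kernel_size = 1,
                       baseline_method = "polynomial",
                       pre_roll = 20, discard_first = TRUE,
                       artifact_guard = 12,
                       cv_radius = 2, cv_residual_threshold = 2,
                       apd_ref = c("onset", "dfdt")) {
  apd_ref <- match.arg(apd_ref)
  windows <- segment_beats(movie, pre_roll = pre_roll,
                           discard_first = discard_first)
  movie <- remove_baseline(movie, method = baseline_method,
                           pre_roll = pre_roll)
  mask <- mask_pixels(movie, snr_threshold = snr_threshold,
                      windows = windows)
  if (kernel_size > 1)
    movie <- spatial_filter(movie, kernel_size = kernel_size, mask = mask)
  nb <- normalize_beats(movie, windows, mask,
                        artifact_guard = artifact_guard)
  apmap <- map_ap_metrics(nb, apd_ref = apd_ref)
  act <- activation_map(apmap)
  field <- local_velocity(act, movie$pixel_pitch, radius = cv_radius,
                          residual_threshold = cv_residual_threshold)
  cv <- tryCatch(mean_cv(field), error = function(e) NA_real_)
  cv_rsd <- tryCatch(conduction_heterogeneity(field),
                     error = function(e) NA_real_)
  summary <- c(apmap$summary, list(cv_mean_cm_s = cv, cv_rsd = cv_rsd))
  structure(list(apmap = apmap, field = field, mask = mask,
                 windows = windows, summary = summary),
            class = "vm_analysis")
}

#' End-to-end calcium-mapping analysis
#'
#' Beat segmentation, drift correction, SNR masking, per-beat
#' normalization, and per-pixel calcium kinetics (time to peak,
#' rest-referenced monoexponential decay rate).
#'
#' @inheritParams analyze_vm
#' @param decay_bounds,decay_r2_min Decay-fit settings, see
#'   [decay_rate()].
#' @return A list of class `ca_analysis`: `camap`, `mask`, `windows`,
#'   `summary`.
#' @export
analyze_ca <- function(movie, snr_threshold = 3, kernel_size = 1,
                       baseline_method = "polynomial",
                       pre_roll = 20, discard_first = TRUE,
                       artifact_guard = 12,
                       decay_bounds = c(0.9, 0.3), decay_r2_min = 0.8) {
  windows <- segment_beats(movie, pre_roll = pre_roll,
                           discard_first = discard_first)
  movie <- remove_baseline(movie, method = baseline_method,
                           pre_roll = pre_roll)
  mask <- mask_pixels(movie, snr_threshold = snr_threshold,
                      windows = windows)
  if (kernel_size > 1)
    movie <- spatial_filter(movie, kernel_size = kernel_size, mask = mask)
  nb <- normalize_beats(movie, windows, mask,
                        artifact_guard = artifact_guard)
  camap <- map_ca_metrics(nb, bounds = decay_bounds, r2_min = decay_r2_min)
  structure(list(camap = camap, mask = mask, windows = windows,
                 summary = camap$summary),
            class = "ca_analysis")
}

#' Spontaneous beating rate of an unpaced movie
#'
#' Detects beats on the field-averaged trace and converts the mean
#' inter-beat interval to BPM.
#'
#' @param movie An unpaced [mapping_movie()].
#' @param snr_threshold SNR mask threshold (masking uses the whole movie).
#' @return A list with `beat_times` (ms) and `bpm`.
#' @export
spontaneous_rate <- function(movie, snr_threshold = 3) {
  mask <- tryCatch(mask_pixels(movie, snr_threshold = snr_threshold),
                   error = function(e) NULL)
  times <- detect_beats(movie, mask = mask)
  list(beat_times = times, bpm = beating_rate(times))
}
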