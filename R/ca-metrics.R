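#' Calcium-transient time to peak
#'
#' Time from activation onset to the transient peak. The onset is the
#' upward crossing of `onset_frac` of the amplitude, extrapolated to the
#' foot of the fitted linear rise (calcium upstrokes are slow, so a
#' threshold-based onset is more stable than a derivative maximum); the
#' peak is the intersection of the fitted rise and early-decay lines,
#' which is robust to noise on the sharp apex.
#'
#' @param y Normalized calcium trace.
#' @param t Sample times, ms.
#' @param onset_frac Onset threshold as a fraction of the amplitude.
#' @return Time to peak, ms (NA when the peak sits at the window edge).
#' @export
time_to_peak <- function(y, t, onset_frac = 0.1) {
  .ca_trace_metrics(y, t, onset_frac = onset_frac)[["ttp"]]
}

#' Calcium decay rate
#'
#' Monoexponential rate of the decay segment between 90% and 30% of the
#' rest-referenced peak amplitude, in 1/s (the reciprocal of the decay time
#' constant tau). Fits with fewer than 5 samples or R-squared below
#' `r2_min` are invalid.
#'
#' @param y Normalized calcium trace.
#' @param t Sample times, ms.
#' @param rest Resting level in the trace's normalized units (from
#'   [normalize_beats()]; 0 for a fully decaying indicator).
#' @param bounds Fit segment bounds as fractions of the rest-referenced
#'   amplitude.
#' @param r2_min Minimum fit R-squared.
#' @param method `"exponential"` (default) fits a monoexponential plus a
#'   free diastolic offset in original units, profiling the rate;
#'   `"loglinear"` is the classical least-squares line through `log(F -
#'   rest)`. The two agree on clean monoexponential decays; the
#'   exponential fit is robust to residual baseline error.
#' @return Decay rate, 1/s (NA when invalid).
#' @export
decay_rate <- function(y, t, rest = 0, bounds = c(0.9, 0.3), r2_min = 0.8,
                       method = c("exponential", "loglinear")) {
  .ca_trace_metrics(y, t, rest = rest, bounds = bounds, r2_min = r2_min,
                    method = method)[["rate"]]
}

#' Per-pixel calcium kinetic maps
#'
#' Runs [time_to_peak()] and [decay_rate()] on every valid pixel of every
#' analyzed beat and averages the per-beat values per pixel. A warning is
#' issued when more than half of the masked pixels yield no valid decay
#' fit (e.g. when a voltage movie is passed by mistake).
#'
#' @param nb A [normalize_beats()] object for a calcium movie.
#' @param bounds,r2_min,method Decay-fit settings, see [decay_rate()].
#' @param min_valid Minimum number of valid pixels.
#' @return An object of class `ca_map`: matrices `time_to_peak` (ms),
#'   `decay_rate` (1/s), `r2`, `valid`, and `summary`.
#' @export
map_ca_metrics <- function(nb, bounds = c(0.9, 0.3), r2_min = 0.8,
                           min_valid = 10,
                           method = c("exponential", "loglinear")) {
  method <- match.arg(method)
  stopifnot(inherits(nb, "normalized_beats"))
  R <- nb$grid[1]; C <- nb$grid[2]
  P <- R * C
  acc <- matrix(0, P, 3, dimnames = list(NULL, c("ttp", "rate", "r2")))
  cnt <- matrix(0L, P, 3)
  maskv <- as.numeric(nb$mask) > 0
  for (b in nb$beats) {
    for (j in which(maskv & b$valid)) {
      m <- .ca_trace_metrics(b$Y[, j], b$t, rest = b$rest[j],
                             bounds = bounds, r2_min = r2_min,
                             method = method)
      ok <- is.finite(m)
      acc[j, ok] <- acc[j, ok] + m[ok]
      cnt[j, ok] <- cnt[j, ok] + 1L
    }
  }
  avg <- acc / ifelse(cnt > 0, cnt, NA)
  maps <- list(time_to_peak = matrix(avg[, "ttp"], R, C),
               decay_rate = matrix(avg[, "rate"], R, C),
               r2 = matrix(avg[, "r2"], R, C))
  valid <- matrix(cnt[, 1] > 0 & cnt[, 2] > 0, R, C)
  n_masked <- sum(maskv)
  if (sum(cnt[, 2] > 0) < 0.5 * n_masked)
    warning("valid decay fits in under half of the masked pixels; ",
            "check that this is a calcium recording")
  if (sum(valid) < min_valid)
    stop(sprintf("fewer than %d valid pixels", min_valid))
  tv <- maps$time_to_peak[is.finite(maps$time_to_peak)]
  rv <- maps$decay_rate[is.finite(maps$decay_rate)]
  summary <- list(n_valid_pixels = sum(valid),
                  ttp_mean_ms = mean(tv), ttp_sd_ms = stats::sd(tv),
                  decay_rate_mean_s = mean(rv),
                  decay_rate_sd_s = stats::sd(rv))
  structure(c(maps, list(valid = valid, mask = nb$mask, summary = summary)),
            class = "ca_map")
}

#' @export
print.ca_map <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<ca_map> %d valid pixels\n", s$n_valid_pixels))
  cat(sprintf("  time to peak: %.1f +/- %.1f ms\n", s$ttp_mean_ms, s$ttp_sd_ms))
  cat(sprintf("  decay rate: %.2f +/- %.2f 1/s\n",
              s$decay_rate_mean_s, s$decay_rate_sd_s))
  invisible(x)
}
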