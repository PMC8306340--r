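#' Segment a paced recording into per-beat analysis windows
#'
#' One window per stimulus, `[stimulus - pre_roll, stimulus + cycle_length -
#' pre_roll - dt]`, clipped to the movie. The first paced beat is discarded
#' by default (pacing-capture transient). For spontaneous recordings pass
#' the beat times from [detect_beats()] as `beat_times`.
#'
#' @param movie A [mapping_movie()].
#' @param pre_roll Pre-stimulus diastolic segment length, ms.
#' @param discard_first Drop the first beat.
#' @param beat_times Optional beat times (ms) overriding the stimulus list.
#' @param cycle_length Override for the window pitch, ms.
#' @return data.frame (class `beat_windows`): `start`, `end`, `stimulus`
#'   (ms).
#' @export
segment_beats <- function(movie, pre_roll = 20, discard_first = TRUE,
                          beat_times = NULL, cycle_length = NULL) {
  stim <- if (is.null(beat_times)) movie$stimulus_times else beat_times
  if (!length(stim))
    stop("no stimulus times: paced mode requires a stimulus list ",
         "(use detect_beats() first for spontaneous recordings)")
  if (is.null(cycle_length)) {
    cycle_length <- if (length(stim) >= 2) stats::median(diff(stim)) else
      movie$cycle_length
  }
  if (!is.finite(cycle_length) || cycle_length <= 0)
    stop("cannot determine cycle length")
  dur <- (dim(movie$data)[1] - 1) * movie$frame_interval
  start <- pmax(stim - pre_roll, 0)
  end <- pmin(stim + cycle_length - pre_roll - movie$frame_interval, dur)
  w <- data.frame(start = start, end = end, stimulus = stim)
  if (discard_first && nrow(w) > 1) w <- w[-1, , drop = FALSE]
  if (any(w$end <= w$start)) stop("degenerate beat window")
  if (nrow(w) > 1 && any(diff(w$start) < (w$end - w$start)[-nrow(w)] - 1e-9))
    stop("overlapping beat windows")
  rownames(w) <- NULL
  class(w) <- c("beat_windows", "data.frame")
  w
}

window_frames <- function(movie, w) {
  t <- frame_times(movie)
  which(t >= w$start - 1e-9 & t <= w$end + 1e-9)
}

#' Mask pixels by signal-to-noise ratio
#'
#' A pixel is valid when its beat-averaged signal amplitude divided by the
#' SD of its high-frequency residual (trace minus a 5-frame moving average)
#' is at least `snr_threshold`. Noiseless pixels with signal are always
#' valid; flat pixels never are.
#'
#' @param movie A [mapping_movie()].
#' @param snr_threshold Minimum amplitude / residual-SD ratio (finite).
#' @param windows Optional [segment_beats()] windows for beat-ensemble
#'   averaging of the amplitude.
#' @return Logical rows x cols matrix (class `pixel_mask`) with attributes
#'   `snr_threshold` and `snr`.
#' @export
mask_pixels <- function(movie, snr_threshold = 3, windows = NULL) {
  if (!is.finite(snr_threshold))
    stop("snr_threshold leaves no valid pixels; lower the threshold")
  M <- trace_matrix(movie)
  sm <- ma_smooth(M, 5L)
  if (!is.null(windows) && nrow(windows) >= 1) {
    L <- min(vapply(seq_len(nrow(windows)), function(k)
      length(window_frames(movie, windows[k, ])), integer(1)))
    ens <- 0
    for (k in seq_len(nrow(windows))) {
      fi <- window_frames(movie, windows[k, ])[seq_len(L)]
      ens <- ens + sm[fi, , drop = FALSE]
    }
    ens <- ens / nrow(windows)
  } else ens <- sm
  amp <- apply(ens, 2L, max) - apply(ens, 2L, min)
  resid <- M - sm
  rsd <- sqrt(pmax(colMeans(resid^2) - colMeans(resid)^2, 0))
  amp_eps <- 1e-9 * max(amp, 1e-300)
  snr <- ifelse(amp <= amp_eps, 0, ifelse(rsd <= 0, Inf, amp / rsd))
  valid <- snr >= snr_threshold & amp > amp_eps
  if (!any(valid))
    stop("no pixels pass the SNR threshold; lower snr_threshold")
  mask <- matrix(valid, grid_dim(movie)[1], grid_dim(movie)[2])
  attr(mask, "snr_threshold") <- snr_threshold
  attr(mask, "snr") <- matrix(snr, grid_dim(movie)[1], grid_dim(movie)[2])
  class(mask) <- c("pixel_mask", class(mask))
  mask
}

#' Remove photobleaching drift
#'
#' Fits a slow drift model to diastolic samples only (so beat morphology is
#' untouched) and subtracts the mean-centered fit, preserving the constant
#' baseline level. Diastolic samples are chosen per channel: for voltage,
#' all samples where the smoothed field-mean trace sits in the lowest 15%
#' of its per-beat range (action potentials repolarize fully, so diastole
#' spans most of each cycle); for calcium, whose diastolic fluorescence may
#' not have decayed fully, only the pre-stimulus segments of the second and
#' later beats (which sit at the steady-state diastolic level), with the
#' polynomial degree capped at one less than the number of such segments.
#'
#' @param movie A [mapping_movie()].
#' @param windows Optional [segment_beats()] windows; derived from the
#'   stimulus list when NULL.
#' @param method `"polynomial"` (degree `degree`) or `"exp_linear"`
#'   (`b0 + b1 t + b2 exp(-t/tau)` with tau profiled on the pooled diastolic
#'   trace).
#' @param degree Polynomial degree.
#' @param pre_roll Pre-stimulus segment length (ms) when windows are
#'   derived here.
#' @return The movie with drift subtracted (constant level preserved).
#' @export
remove_baseline <- function(movie, windows = NULL,
                            method = c("polynomial", "exp_linear"),
                            degree = 2, pre_roll = 20) {
  method <- match.arg(method)
  stim <- movie$stimulus_times
  if (is.null(windows)) {
    if (length(stim) < 2)
      stop("need at least 2 beats to fit a stable baseline")
    windows <- data.frame(start = pmax(stim - pre_roll, 0),
                          end = pmin(stim + stats::median(diff(stim)),
                                     max(frame_times(movie))),
                          stimulus = stim)
  }
  t <- frame_times(movie)
  M <- trace_matrix(movie)
  if (identical(movie$channel, "voltage")) {
    g <- ma_smooth(rowMeans(M), 5L)
    dia <- integer(0)
    for (k in seq_len(nrow(windows))) {
      fi <- which(t >= windows$start[k] - 1e-9 & t <= windows$end[k] + 1e-9)
      gk <- g[fi]
      thr <- min(gk) + 0.02 * (max(gk) - min(gk))
      low <- gk <= thr
      # erode by two frames so samples bordering the action potential
      # (upstroke foot, repolarization tail) never enter the fit
      nlow <- length(low)
      eroded <- low
      for (s_ in c(-2L, -1L, 1L, 2L)) {
        sh <- rep(TRUE, nlow)
        src <- seq_len(nlow) + s_
        ok <- src >= 1L & src <= nlow
        sh[ok] <- low[src[ok]]
        eroded <- eroded & sh
      }
      if (sum(eroded) < 5L) eroded <- low
      dia <- c(dia, fi[eroded])
    }
  } else {
    dia <- integer(0)
    n_seg <- 0L
    use <- if (nrow(windows) > 1) 2:nrow(windows) else 1L
    for (k in use) {
      fi <- which(t >= windows$start[k] - 1e-9 & t < windows$stimulus[k] - 1e-9)
      if (length(fi)) n_seg <- n_seg + 1L
      dia <- c(dia, fi)
    }
    degree <- max(1L, min(degree, n_seg - 1L))
  }
  dia <- sort(unique(dia))
  if (length(dia) < degree + 2)
    stop("too few diastolic samples to fit the baseline")
  tc <- (t - mean(t[dia])) / 1000
  X <- switch(method,
    polynomial = stats::poly(tc, degree, raw = TRUE),
    exp_linear = {
      g <- rowMeans(M[dia, , drop = FALSE])
      sse <- function(tau) {
        Xd <- cbind(tc[dia], exp(-t[dia] / tau))
        r <- stats::lm.fit(cbind(1, Xd), g)$residuals
        sum(r^2)
      }
      tau <- stats::optimize(sse, c(50, 60000))$minimum
      cbind(tc, exp(-t / tau))
    })
  Xd <- cbind(1, X[dia, , drop = FALSE])
  coef <- tryCatch(qr.solve(Xd, M[dia, , drop = FALSE]),
                   error = function(e) NULL)
  if (is.null(coef)) {
    warning("baseline fit failed; falling back to linear detrend")
    Xd <- cbind(1, tc[dia])
    coef <- qr.solve(Xd, M[dia, , drop = FALSE])
    X <- cbind(tc)
  }
  fit <- cbind(1, X) %*% coef
  fit <- sweep(fit, 2L, colMeans(fit))   # keep the constant level
  out <- movie
  out$data <- array(M - fit, dim(movie$data))
  out
}

#' Masked Gaussian spatial smoothing
#'
#' Per-frame Gaussian filtering restricted to valid pixels: weights of
#' invalid (or out-of-frame) pixels are renormalized away so they never
#' leak into valid ones. `kernel_size = 1` is the identity.
#'
#' @param movie A [mapping_movie()].
#' @param kernel_size Odd kernel side length, pixels.
#' @param mask Optional [mask_pixels()] mask.
#' @param sigma Gaussian sigma in pixels (default `kernel_size / 3`).
#' @return The smoothed movie.
#' @export
spatial_filter <- function(movie, kernel_size = 3, mask = NULL, sigma = NULL) {
  if (kernel_size %% 2 == 0) stop("kernel_size must be odd")
  if (kernel_size == 1) return(movie)
  if (is.null(sigma)) sigma <- kernel_size / 3
  r <- (kernel_size - 1L) %/% 2L
  off <- -r:r
  k1 <- exp(-off^2 / (2 * sigma^2))
  gd <- grid_dim(movie)
  R <- gd[1]; C <- gd[2]
  if (is.null(mask)) mask <- matrix(TRUE, R, C)
  mv <- as.numeric(mask)
  M <- trace_matrix(movie)
  Fn <- nrow(M)
  num <- matrix(0, Fn, R * C)
  den <- numeric(R * C)
  for (dr in off) for (dc in off) {
    w <- k1[dr + r + 1L] * k1[dc + r + 1L]
    rt <- max(1L, 1L - dr):min(R, R - dr)      # target rows
    ct <- max(1L, 1L - dc):min(C, C - dc)
    rs <- rt + dr; cs <- ct + dc               # source rows/cols
    tgt <- as.integer(outer(rt, (ct - 1L) * R, "+"))
    src <- as.integer(outer(rs, (cs - 1L) * R, "+"))
    wsrc <- w * mv[src]
    num[, tgt] <- num[, tgt] + sweep(M[, src, drop = FALSE], 2L, wsrc, "*")
    den[tgt] <- den[tgt] + wsrc
  }
  ok <- den > 0 & mv > 0
  out <- M
  out[, ok] <- sweep(num[, ok, drop = FALSE], 2L, den[ok], "/")
  res <- movie
  res$data <- array(out, dim(movie$data))
  res
}

#' Per-beat amplitude normalization
#'
#' Within each beat window the trace is rescaled to `[0, 1]`: the baseline
#' `F_min` is the mean of the pre-stimulus diastolic samples and `F_max`
#' the in-window maximum, so a noiseless beat has diastole exactly 0 and
#' peak exactly 1. Pixels with non-positive amplitude in a window are
#' flagged invalid for that beat. The diastolic resting level of the
#' lead-in before the first stimulus is retained (in normalized units) for
#' indicators whose diastolic fluorescence has not fully decayed.
#'
#' @param movie Baseline-corrected [mapping_movie()].
#' @param windows [segment_beats()] windows.
#' @param mask Optional [mask_pixels()] mask.
#' @param artifact_guard Samples within `[stimulus, stimulus +
#'   artifact_guard]` ms never enter baseline estimation.
#' @return An object of class `normalized_beats`: per beat, relative times
#'   `t` (ms, 0 at the stimulus), normalized trace matrix `Y` (frames x
#'   pixels), amplitudes, baselines, validity, and `rest` (resting level in
#'   the beat's normalized units).
#' @export
normalize_beats <- function(movie, windows, mask = NULL, artifact_guard = 12) {
  M <- trace_matrix(movie)
  t <- frame_times(movie)
  P <- ncol(M)
  if (is.null(mask)) mask <- matrix(TRUE, grid_dim(movie)[1], grid_dim(movie)[2])
  stim_all <- sort(unique(c(movie$stimulus_times, windows$stimulus)))
  lead <- which(t < stim_all[1] - 1e-9 & t < windows$start[1] - 1e-9)
  rest_counts <- if (length(lead) >= 3) colMeans(M[lead, , drop = FALSE]) else NULL

  beats <- vector("list", nrow(windows))
  for (k in seq_len(nrow(windows))) {
    w <- windows[k, ]
    fi <- window_frames(movie, w)
    pre <- which(t[fi] < w$stimulus - 1e-9 &
                 !(t[fi] >= w$stimulus & t[fi] <= w$stimulus + artifact_guard))
    if (length(pre) < 1) pre <- 1L
    Y <- M[fi, , drop = FALSE]
    f0 <- colMeans(Y[pre, , drop = FALSE])
    Y <- Y - rep(f0, each = length(fi))
    amp <- apply(Y, 2L, max)
    valid <- amp > 1e-12 & as.numeric(mask) > 0
    ampc <- ifelse(valid, amp, 1)
    Y <- Y / rep(ampc, each = length(fi))
    rest <- if (is.null(rest_counts)) rep(0, P) else
      ifelse(valid, (rest_counts - f0) / ampc, 0)
    beats[[k]] <- list(t = t[fi] - w$stimulus, Y = Y, f0 = f0, amp = amp,
                       valid = valid, rest = rest)
  }
  structure(list(beats = beats, windows = windows, mask = mask,
                 frame_interval = movie$frame_interval,
                 grid = grid_dim(movie), channel = movie$channel),
            class = "normalized_beats")
}

#' Detect spontaneous beats from the field-averaged trace
#'
#' Detrends and smooths the masked mean trace, then takes upstroke midpoint
#' (50% amplitude) upward crossings with a refractory lockout.
#'
#' @param movie A [mapping_movie()].
#' @param mask Optional [mask_pixels()] mask.
#' @param min_interval Refractory lockout, ms.
#' @param threshold Crossing level as a fraction of the 1-99% amplitude
#'   range.
#' @return Beat times, ms.
#' @export
detect_beats <- function(movie, mask = NULL, min_interval = 250,
                         threshold = 0.5) {
  M <- trace_matrix(movie)
  if (!is.null(mask)) M <- M[, as.numeric(mask) > 0, drop = FALSE]
  g <- rowMeans(M)
  t <- frame_times(movie)
  wslow <- min(length(g), 2L * (round(1500 / movie$frame_interval) %/% 2L) + 1L)
  g <- g - ma_smooth(g, wslow)
  gs <- ma_smooth(g, 5L)
  q <- stats::quantile(gs, c(0.01, 0.99), names = FALSE)
  if (diff(q) <= max(1e-9, 1e-6 * max(abs(gs))))
    stop("flat trace: no beats detected")
  z <- (gs - q[1]) / diff(q)
  up <- which(z[-length(z)] < threshold & z[-1] >= threshold)
  times <- t[up] + movie$frame_interval *
    (threshold - z[up]) / (z[up + 1L] - z[up])
  if (length(times) > 1) {
    keep <- c(TRUE, diff(times) >= min_interval)
    while (!all(keep)) {
      times <- times[keep]
      keep <- c(TRUE, diff(times) >= min_interval)
    }
  }
  if (length(times) < 3)
    stop("fewer than 3 beats detected")
  times
}
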