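# Per-trace estimators shared by the AP and calcium metric maps.
#
# Design notes (numerical choices):
# * Activation is the time of maximum first derivative (central
#   differences), refined by quadratic interpolation over the three
#   samples around the discrete maximum.
# * The amplitude reference A for repolarization thresholds is the
#   intersection of a line fitted to the upstroke with a line fitted to
#   early repolarization. Unlike the raw in-window maximum, this estimate
#   is unbiased under additive noise, which matters because a bias e in A
#   shifts an APD crossing by roughly e * (1 - level) / |repolarization
#   slope|.
# * Level crossings are located on a 5-frame moving average (sustained:
#   two consecutive sub-threshold samples), then refined by a local
#   least-squares line on the raw samples, which is unbiased on a locally
#   linear segment.

.lfit <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  vx <- sum((x - mx)^2)
  if (vx <= 0) return(c(my, 0))
  b <- sum((x - mx) * (y - my)) / vx
  c(my - b * mx, b)
}

# core AP-trace decomposition; y normalized, t in ms (uniform)
.ap_trace_core <- function(y, t) {
  n <- length(y)
  if (n < 7L) return(NULL)
  dt <- t[2] - t[1]
  d <- c(NA, (y[3:n] - y[1:(n - 2)]) / (2 * dt), NA)
  imax <- which.max(d[2:(n - 1)]) + 1L
  vmax <- d[imax]
  if (!is.finite(vmax) || vmax <= 0) return(NULL)
  flagged <- sum(d[2:(n - 1)] == vmax, na.rm = TRUE) > 1L

  shift <- 0
  if (imax > 2L && imax < n - 1L) {
    den <- d[imax - 1L] - 2 * d[imax] + d[imax + 1L]
    if (is.finite(den) && den < 0) {
      shift <- 0.5 * (d[imax - 1L] - d[imax + 1L]) / den
      shift <- max(min(shift, 1), -1)
    }
  }
  act <- t[imax] + shift * dt

  # upstroke line through the ramp samples (derivative > half maximum)
  # (the quadratic-refined act above is replaced below by the upstroke-line
  # midpoint crossing when the line fit is available: it locates the center
  # of the maximum-derivative ramp independently of the sampling phase)
  lo <- imax
  while (lo > 2L && is.finite(d[lo - 1L]) && d[lo - 1L] > 0.5 * vmax) lo <- lo - 1L
  hi <- imax
  while (hi < n - 1L && is.finite(d[hi + 1L]) && d[hi + 1L] > 0.5 * vmax) hi <- hi + 1L
  up <- if (hi > lo) .lfit(t[lo:hi], y[lo:hi]) else
    c(y[imax] - vmax * t[imax], vmax)

  # apex: derivative (3-point smoothed) falls below 20% of its maximum
  dpad <- d
  dpad[1] <- d[2]; dpad[n] <- d[n - 1L]
  ds <- dpad
  ds[2:(n - 1)] <- (dpad[1:(n - 2)] + dpad[2:(n - 1)] + dpad[3:n]) / 3
  i_ap <- imax
  while (i_ap < n - 2L && ds[i_ap] > 0.2 * vmax) i_ap <- i_ap + 1L

  # early-repolarization line
  j1 <- min(i_ap + 1L, n - 2L)
  j2 <- min(j1 + max(3L, round(40 / dt)), n)
  rp <- .lfit(t[j1:j2], y[j1:j2])

  denom <- up[2] - rp[2]
  if (is.finite(denom) && denom > 1e-9) {
    t_a <- (rp[1] - up[1]) / denom
    A <- up[1] + up[2] * t_a
  } else {
    t_a <- t[i_ap]
    A <- max(y)
  }
  if (!is.finite(A) || A <= 0 || t_a < t[1] || t_a > t[j2]) {
    t_a <- t[i_ap]
    A <- max(y)
  }
  foot <- act
  if (up[2] > 0) {
    act_mid <- (0.5 * A - up[1]) / up[2]
    if (is.finite(act_mid) && abs(act_mid - act) <= 2 * dt) act <- act_mid
    f <- -up[1] / up[2]
    if (is.finite(f) && f <= act && act - f <= A / up[2]) foot <- f
  }
  # reported upstroke velocity: slope of the line through the
  # maximum-derivative ramp samples. The raw max central difference is
  # noise-inflated (a maximum over noisy differences) and saturates at
  # 1/(2 dt) for upstrokes shorter than two frames; the fitted slope is
  # unbiased for a locally linear upstroke.
  vfit <- if (hi > lo && up[2] > 0) up[2] else vmax
  list(t = t, y = y, dt = dt, n = n, act = act, foot = foot, vmax = vmax,
       vfit = vfit, flagged = flagged, i_ap = i_ap, t_apex = t_a, A = A)
}

# downward crossing of (1 - level) * A after the apex; NA if none.
# Localized on a 9-frame moving average (sustained: two consecutive
# sub-threshold samples), then refined by a least-squares line on the raw
# samples just past the crossing. The one-sided window keeps the fit on a
# single repolarization segment, so the refinement is unbiased even when
# the crossing sits at a change of repolarization slope.
.ap_crossing <- function(core, level) {
  thr <- (1 - level) * core$A
  y <- core$y; t <- core$t; n <- core$n
  ys <- ma_smooth(y, 9L)
  i0 <- core$i_ap
  idx <- seq.int(i0, n - 1L)
  below <- ys[idx] < thr & ys[idx + 1L] < thr
  hit <- which(below)
  if (!length(hit)) return(NA_real_)
  i <- idx[hit[1]]
  w <- i:min(n, i + max(5L, round(24 / core$dt)))
  fit <- .lfit(t[w], y[w])
  if (fit[2] < 0) {
    tc <- (thr - fit[1]) / fit[2]
    if (tc >= t[max(i - 5L, 1L)] && tc <= t[min(i + 5L, n)]) return(tc)
  }
  # fall back to interpolation between the straddling samples
  j <- i
  while (j > i0 && y[j] < thr) j <- j - 1L
  if (y[j] < thr || j >= n) return(t[i])
  t[j] + core$dt * (y[j] - thr) / (y[j] - y[j + 1L])
}

# apd_ref: "onset" references APDs to the extrapolated upstroke foot (the
# activation onset the template truth is defined from); "dfdt" references
# them to the maximum-derivative activation time.
.ap_trace_metrics <- function(y, t, levels = c(0.3, 0.8),
                              apd_ref = c("onset", "dfdt")) {
  apd_ref <- match.arg(apd_ref)
  core <- .ap_trace_core(y, t)
  if (is.null(core))
    return(c(act = NA_real_, vmax = NA_real_,
             stats::setNames(rep(NA_real_, length(levels)),
                             paste0("apd", round(100 * levels)))))
  ref <- if (apd_ref == "onset") core$foot else core$act
  cr <- vapply(levels, function(l) .ap_crossing(core, l), numeric(1))
  apd <- cr - ref
  apd[!is.na(apd) & apd <= 0] <- NA_real_
  c(act = core$act, vmax = core$vfit,
    stats::setNames(apd, paste0("apd", round(100 * levels))))
}

# calcium transient: time to peak (foot to apex) and monoexponential decay
# rate fitted log-linearly on the rest-referenced 90-30% segment
.ca_trace_metrics <- function(y, t, rest = 0, bounds = c(0.9, 0.3),
                              r2_min = 0.8, onset_frac = 0.1,
                              method = c("exponential", "loglinear")) {
  method <- match.arg(method)
  n <- length(y)
  out <- c(ttp = NA_real_, rate = NA_real_, r2 = NA_real_)
  if (n < 10L) return(out)
  dt <- t[2] - t[1]
  ys <- ma_smooth(y, 5L)
  i_pk <- which.max(ys)
  if (i_pk <= 3L || i_pk >= n - 3L) return(out)   # peak at window edge
  A0 <- ys[i_pk]
  if (A0 <= 0) return(out)

  i25 <- which(ys[1:i_pk] >= 0.25 * A0)[1]
  i75 <- which(ys[1:i_pk] >= 0.75 * A0)[1]
  if (is.na(i25) || is.na(i75)) return(out)
  ri <- max(1L, i25 - 1L):min(i_pk, i75 + 1L)
  if (length(ri) < 2L) ri <- max(1L, i_pk - 2L):i_pk
  up <- .lfit(t[ri], y[ri])
  if (up[2] <= 0) return(out)

  j1 <- min(i_pk + 1L, n - 2L)
  j2 <- min(j1 + max(3L, round(40 / dt)), n)
  dn <- .lfit(t[j1:j2], y[j1:j2])
  denom <- up[2] - dn[2]
  if (is.finite(denom) && denom > 1e-9) {
    t_a <- (dn[1] - up[1]) / denom
    A <- up[1] + up[2] * t_a
  } else {
    t_a <- t[i_pk]; A <- A0
  }
  if (!is.finite(A) || A <= 0 || t_a < t[1] || t_a > t[j2]) {
    t_a <- t[i_pk]; A <- A0
  }

  # onset: upward crossing of onset_frac * A, extrapolated to the foot of
  # the linear rise
  t_foot <- (onset_frac * A - up[1]) / up[2] - onset_frac * A / up[2]
  ttp <- t_a - t_foot
  if (is.finite(ttp) && ttp > 0) out["ttp"] <- ttp

  z <- y - rest
  Az <- A - rest
  if (Az <= 0) return(out)
  i_dec <- which(t > t_a)
  k1 <- i_dec[which(z[i_dec] <= bounds[1] * Az)[1]]
  if (is.na(k1)) return(out)
  after <- i_dec[i_dec >= k1]
  stop_i <- after[which(z[after] < bounds[2] * Az)[1]]
  seg <- if (is.na(stop_i)) after else after[after < stop_i]
  if (length(seg) < 5L) return(out)
  ts <- t[seg] - t[seg][1]
  ysg <- y[seg]

  if (method == "exponential") {
    # monoexponential-plus-offset fit, profiling the rate: for fixed k the
    # model a exp(k t) + c is linear in (a, c). Fitting in original units
    # keeps the noise homoscedastic, and the free offset absorbs residual
    # baseline error that a log-linear fit is exquisitely sensitive to.
    sse_k <- function(lk) {
      e <- exp(-exp(lk) * ts)
      f <- stats::lm.fit(cbind(1, e), ysg)
      sum(f$residuals^2)
    }
    lk <- tryCatch(stats::optimize(sse_k, log(c(1e-5, 0.05)))$minimum,
                   error = function(e) NA_real_)
    if (!is.finite(lk)) return(out)
    k <- exp(lk)
    # a rate pinned at the search floor means the segment has no resolvable
    # exponential curvature (e.g. a linear repolarization, not a Ca decay)
    if (k < 1.5e-5) return(out)
    e <- exp(-k * ts)
    f <- stats::lm.fit(cbind(1, e), ysg)
    if (f$coefficients[2] <= 0) return(out)
    sst <- sum((ysg - mean(ysg))^2)
    r2 <- if (sst > 0) 1 - sum(f$residuals^2) / sst else 1
    if (r2 < r2_min) { out["r2"] <- r2; return(out) }
    out["rate"] <- k * 1000
    out["r2"] <- r2
    return(out)
  }

  zs <- ysg - rest
  if (any(zs <= 0)) return(out)
  lz <- log(zs)
  fit <- .lfit(ts, lz)
  if (fit[2] >= 0) return(out)
  pred <- fit[1] + fit[2] * ts
  sst <- sum((lz - mean(lz))^2)
  r2 <- if (sst > 0) 1 - sum((lz - pred)^2) / sst else 1
  if (r2 < r2_min) { out["r2"] <- r2; return(out) }
  out["rate"] <- -fit[2] * 1000
  out["r2"] <- r2
  out
}
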