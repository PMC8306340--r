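#' Beat-averaged activation-time raster
#'
#' @param apmap An [map_ap_metrics()] result.
#' @return Matrix of activation times (ms), NA outside the valid mask.
#' @export
activation_map <- function(apmap) {
  stopifnot(inherits(apmap, "ap_map"))
  act <- apmap$activation_time
  act[!(apmap$mask & is.finite(act))] <- NA_real_
  act
}

#' Local conduction-velocity vector field
#'
#' Fits a least-squares plane `T(x, y) = a + b x + c y` (x, y in mm) to the
#' activation times in a `(2 radius + 1)^2` neighborhood of each pixel.
#' The local velocity is `(b, c) / (b^2 + c^2)` mm/ms and the speed its
#' magnitude `1 / sqrt(b^2 + c^2)`. Pixels are invalid when fewer than
#' `min_neighbor_frac` of the neighborhood is populated, when the plane RMS
#' residual exceeds `residual_threshold` ms, or when the fitted gradient is
#' degenerate (flat plane).
#'
#' @param act Activation-time matrix, ms (NA = invalid).
#' @param pixel_pitch Pixel pitch, mm.
#' @param radius Neighborhood half-width in pixels.
#' @param residual_threshold Maximum RMS plane residual, ms.
#' @param min_neighbor_frac Minimum populated fraction of the neighborhood.
#' @return An object of class `velocity_field`: matrices `vx`, `vy` (mm/ms,
#'   along cols and rows respectively), `speed` (mm/ms), `residual` (ms),
#'   `valid`.
#' @export
local_velocity <- function(act, pixel_pitch, radius = 2,
                           residual_threshold = 2, min_neighbor_frac = 0.5) {
  stopifnot(radius >= 1, pixel_pitch > 0)
  R <- nrow(act); C <- ncol(act)
  k <- 2L * radius + 1L
  off <- -radius:radius
  # neighborhood design: x along columns, y along rows, in mm
  xs <- rep(off, each = k) * pixel_pitch
  ys <- rep(off, times = k) * pixel_pitch
  X <- cbind(1, xs, ys)

  # gather neighborhoods of every pixel into a k^2 x P matrix (padded NA)
  pad <- matrix(NA_real_, R + 2L * radius, C + 2L * radius)
  pad[radius + seq_len(R), radius + seq_len(C)] <- act
  P <- R * C
  N <- matrix(NA_real_, k * k, P)
  row0 <- rep(seq_len(R), times = C)
  col0 <- rep(seq_len(C), each = R)
  i <- 0L
  for (dc in off) for (dr in off) {
    i <- i + 1L
    N[i, ] <- pad[cbind(row0 + radius + dr, col0 + radius + dc)]
  }
  # order above: dr varies fastest within dc -> matches ys within xs
  ok <- is.finite(N)
  n_ok <- colSums(ok)
  need <- ceiling(min_neighbor_frac * k * k)

  vx <- vy <- speed <- resid <- rep(NA_real_, P)
  valid <- rep(FALSE, P)
  XtX_full <- crossprod(X)
  full <- n_ok == k * k
  if (any(full)) {
    B <- solve(XtX_full, t(X)) %*% N[, full, drop = FALSE]  # 3 x n coefs
    fitted <- X %*% B
    r2 <- sqrt(colMeans((N[, full, drop = FALSE] - fitted)^2))
    g2 <- B[2, ]^2 + B[3, ]^2
    vx[full] <- B[2, ] / g2
    vy[full] <- B[3, ] / g2
    speed[full] <- 1 / sqrt(g2)
    resid[full] <- r2
    valid[full] <- g2 > 1e-12 & r2 <= residual_threshold
  }
  partial <- which(!full & n_ok >= pmax(need, 4L))
  for (j in partial) {
    sel <- ok[, j]
    Xj <- X[sel, , drop = FALSE]
    fit <- tryCatch(stats::lm.fit(Xj, N[sel, j]), error = function(e) NULL)
    if (is.null(fit) || any(is.na(fit$coefficients))) next
    b <- fit$coefficients[2]; cc <- fit$coefficients[3]
    g2 <- b^2 + cc^2
    if (!is.finite(g2) || g2 <= 1e-12) next
    r2 <- sqrt(mean(fit$residuals^2))
    vx[j] <- b / g2; vy[j] <- cc / g2
    speed[j] <- 1 / sqrt(g2); resid[j] <- r2
    valid[j] <- r2 <= residual_threshold
  }
  valid[!is.finite(speed)] <- FALSE
  shape <- function(v) matrix(v, R, C)
  structure(list(vx = shape(vx), vy = shape(vy), speed = shape(speed),
                 residual = shape(resid), valid = shape(valid),
                 pixel_pitch = pixel_pitch, radius = radius),
            class = "velocity_field")
}

#' Mean conduction velocity
#'
#' Mean of valid local speeds, converted to cm/s (1 mm/ms = 100 cm/s).
#'
#' @param field A [local_velocity()] field.
#' @param mask Optional extra logical mask.
#' @param min_vectors Minimum number of valid vectors.
#' @return Mean conduction velocity, cm/s.
#' @export
mean_cv <- function(field, mask = NULL, min_vectors = 10) {
  v <- field$speed
  keep <- field$valid & is.finite(v)
  if (!is.null(mask)) keep <- keep & mask
  v <- v[keep]
  if (length(v) < min_vectors)
    stop(sprintf("fewer than %d valid velocity vectors", min_vectors))
  mean(v) * 100
}

#' Conduction heterogeneity
#'
#' Relative standard deviation (sample SD / mean) of the valid local
#' speeds, mirroring the upstroke-velocity heterogeneity metric.
#'
#' @inheritParams mean_cv
#' @return RSD of local conduction speeds (dimensionless).
#' @export
conduction_heterogeneity <- function(field, mask = NULL, min_vectors = 10) {
  v <- field$speed
  keep <- field$valid & is.finite(v)
  if (!is.null(mask)) keep <- keep & mask
  v <- v[keep]
  if (length(v) < min_vectors)
    stop(sprintf("fewer than %d valid velocity vectors", min_vectors))
  stats::sd(v) / mean(v)
}
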