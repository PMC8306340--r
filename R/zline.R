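#' Configuration for synthetic striation (Z-line) images
#'
#' Bright, anti-aliased line segments of exactly recorded length on a noisy
#' background, emulating alpha-actinin-immunopositive Z-lines in a confocal
#' field.
#'
#' @param image_size Image size in pixels, `c(height, width)` or a scalar.
#' @param pixel_size_um Pixel size, micrometers per pixel.
#' @param segments data.frame with columns `row`, `col` (segment center,
#'   px), `angle` (degrees), `length_um`, and optionally `width_um`
#'   (default 0.15) and `intensity` (default 1).
#' @param background_sd Gaussian background noise SD (intensity units).
#' @param seed Integer seed for the noise.
#' @return An object of class `zline_sim_config`.
#' @export
zline_sim_config <- function(image_size, pixel_size_um, segments,
                             background_sd = 0.05, seed = NULL) {
  if (length(image_size) == 1L) image_size <- c(image_size, image_size)
  stopifnot(all(image_size >= 4), pixel_size_um > 0, background_sd >= 0,
            is.data.frame(segments) || is.null(segments))
  if (is.null(segments))
    segments <- data.frame(row = numeric(0), col = numeric(0),
                           angle = numeric(0), length_um = numeric(0))
  if (nrow(segments)) {
    stopifnot(all(c("row", "col", "angle", "length_um") %in% names(segments)))
    if (is.null(segments$width_um)) segments$width_um <- 0.15
    if (is.null(segments$intensity)) segments$intensity <- 1
    if (any(segments$length_um <= 0)) stop("segment lengths must be > 0")
  }
  structure(list(image_size = image_size, pixel_size_um = pixel_size_um,
                 segments = segments, background_sd = background_sd,
                 seed = seed),
            class = "zline_sim_config")
}

segment_endpoints <- function(seg, pixel_size_um) {
  half <- seg$length_um / (2 * pixel_size_um)
  th <- seg$angle * pi / 180
  list(r1 = seg$row - half * sin(th), c1 = seg$col - half * cos(th),
       r2 = seg$row + half * sin(th), c2 = seg$col + half * cos(th))
}

#' Place random non-overlapping Z-line segments
#'
#' Rejection-samples segment centers and orientations so that no two
#' segments come closer than the sum of their half-widths plus `min_sep_um`.
#'
#' @param n Number of segments.
#' @param image_size Image size in pixels (scalar or `c(h, w)`).
#' @param pixel_size_um Micrometers per pixel.
#' @param length_mean_um,length_sd_um Normal distribution of true lengths.
#' @param width_um Stroke width.
#' @param min_sep_um Minimum separation between strokes.
#' @param margin_px Keep segments this far from the image border.
#' @param seed Integer seed.
#' @return A segments data.frame suitable for [zline_sim_config()].
#' @export
random_zline_segments <- function(n, image_size, pixel_size_um,
                                  length_mean_um, length_sd_um = 0,
                                  width_um = 0.15, min_sep_um = 0.5,
                                  margin_px = 12, seed = NULL) {
  if (length(image_size) == 1L) image_size <- c(image_size, image_size)
  if (!is.null(seed)) set.seed(seed)
  placed <- list()
  tries <- 0L
  while (length(placed) < n && tries < 200L * n) {
    tries <- tries + 1L
    len <- max(stats::rnorm(1, length_mean_um, length_sd_um), 4 * pixel_size_um)
    half_px <- len / (2 * pixel_size_um)
    cand <- data.frame(
      row = stats::runif(1, margin_px + half_px, image_size[1] - margin_px - half_px),
      col = stats::runif(1, margin_px + half_px, image_size[2] - margin_px - half_px),
      angle = stats::runif(1, 0, 180), length_um = len,
      width_um = width_um, intensity = 1)
    ok <- TRUE
    for (p in placed) {
      if (segment_min_dist_px(cand, p, pixel_size_um) * pixel_size_um <
          (cand$width_um + p$width_um) / 2 + min_sep_um) { ok <- FALSE; break }
    }
    if (ok) placed[[length(placed) + 1L]] <- cand
  }
  if (length(placed) < n)
    stop("could not place the requested number of non-overlapping segments")
  do.call(rbind, placed)
}

# minimum distance (px) between two segments, by dense sampling
segment_min_dist_px <- function(a, b, pixel_size_um) {
  pa <- segment_endpoints(a, pixel_size_um)
  pb <- segment_endpoints(b, pixel_size_um)
  s <- seq(0, 1, length.out = 25)
  ra <- pa$r1 + s * (pa$r2 - pa$r1); ca <- pa$c1 + s * (pa$c2 - pa$c1)
  rb <- pb$r1 + s * (pb$r2 - pb$r1); cb <- pb$c1 + s * (pb$c2 - pb$c1)
  min(sqrt(outer(ra, rb, "-")^2 + outer(ca, cb, "-")^2))
}

#' Render a synthetic striation image
#'
#' Draws each segment as a flat-capped, anti-aliased stroke; the drawn
#' length equals the recorded truth exactly. Errors if any two strokes
#' overlap.
#'
#' @param config A [zline_sim_config()].
#' @return A list: `image` (matrix, attribute `pixel_size_um`),
#'   `lengths_um` (true lengths), `segments`.
#' @export
simulate_zline_image <- function(config) {
  stopifnot(inherits(config, "zline_sim_config"))
  h <- config$image_size[1]; w <- config$image_size[2]
  segs <- config$segments
  n <- nrow(segs)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      d_um <- segment_min_dist_px(segs[i, ], segs[j, ], config$pixel_size_um) *
        config$pixel_size_um
      if (d_um < (segs$width_um[i] + segs$width_um[j]) / 2)
        stop("overlapping segments in zline_sim_config")
    }
  }
  img <- matrix(0, h, w)
  for (i in seq_len(nrow(segs))) {
    seg <- segs[i, ]
    p <- segment_endpoints(seg, config$pixel_size_um)
    halfw <- seg$width_um / (2 * config$pixel_size_um)
    r0 <- max(1L, floor(min(p$r1, p$r2) - halfw - 2))
    r1 <- min(h, ceiling(max(p$r1, p$r2) + halfw + 2))
    c0 <- max(1L, floor(min(p$c1, p$c2) - halfw - 2))
    c1 <- min(w, ceiling(max(p$c1, p$c2) + halfw + 2))
    rr <- r0:r1; cc <- c0:c1
    R <- matrix(rr, length(rr), length(cc))
    C <- matrix(cc, length(rr), length(cc), byrow = TRUE)
    dr <- p$r2 - p$r1; dc <- p$c2 - p$c1
    len_px <- sqrt(dr^2 + dc^2)
    tpar <- ((R - p$r1) * dr + (C - p$c1) * dc) / len_px^2
    dlat <- abs((C - p$c1) * dr - (R - p$r1) * dc) / len_px
    dax <- pmax(0, abs(tpar - 0.5) * len_px - len_px / 2)
    cov <- pmin(pmax(0.5 + (halfw - dlat), 0), 1) *
      pmin(pmax(1 - dax, 0), 1)
    img[rr, cc] <- pmax(img[rr, cc], seg$intensity * cov)
  }
  if (config$background_sd > 0) {
    if (!is.null(config$seed)) set.seed(config$seed)
    img <- img + stats::rnorm(length(img), 0, config$background_sd)
  }
  attr(img, "pixel_size_um") <- config$pixel_size_um
  list(image = img, lengths_um = segs$length_um, segments = segs)
}

#' Randomly select square regions of interest
#'
#' Uniformly random, non-overlapping, axis-aligned square ROIs with a
#' seed-reproducible layout (the scripted ROI selection used for Z-line
#' scoring).
#'
#' @param image Image matrix.
#' @param pixel_size_um Micrometers per pixel.
#' @param roi_size_um ROI side length, micrometers (default 20).
#' @param n_rois Number of ROIs.
#' @param seed Integer seed.
#' @param max_tries Placement attempts before giving up.
#' @return data.frame `row0`, `col0`, `size_px` (top-left corners, 1-based).
#' @export
select_rois <- function(image, pixel_size_um, roi_size_um = 20, n_rois = 2,
                        seed = NULL, max_tries = 2000L) {
  size_px <- round(roi_size_um / pixel_size_um)
  h <- nrow(image); w <- ncol(image)
  if (h < size_px || w < size_px)
    stop("image smaller than the requested ROI")
  if (!is.null(seed)) set.seed(seed)
  rois <- data.frame(row0 = integer(0), col0 = integer(0))
  tries <- 0L
  stuck <- 0L
  while (nrow(rois) < n_rois && tries < max_tries) {
    tries <- tries + 1L
    r0 <- sample.int(h - size_px + 1L, 1L)
    c0 <- sample.int(w - size_px + 1L, 1L)
    overlap <- nrow(rois) && any(abs(rois$row0 - r0) < size_px &
                                 abs(rois$col0 - c0) < size_px)
    if (!overlap) {
      rois <- rbind(rois, data.frame(row0 = r0, col0 = c0))
      stuck <- 0L
    } else {
      stuck <- stuck + 1L
      # an unlucky early placement can block the rest; restart the layout
      if (stuck >= 100L) {
        rois <- rois[0, , drop = FALSE]
        stuck <- 0L
      }
    }
  }
  if (nrow(rois) < n_rois)
    stop("could not place the requested number of non-overlapping ROIs")
  rois$size_px <- size_px
  rois
}

crop_roi <- function(image, roi) {
  image[roi$row0:(roi$row0 + roi$size_px - 1L),
        roi$col0:(roi$col0 + roi$size_px - 1L)]
}

# Guo-Hall thinning of a binary matrix (preserves diagonal strokes, which
# Zhang-Suen erodes away)
gh_thin <- function(B) {
  B <- B != 0
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      nr <- nrow(B); nc <- ncol(B)
      P <- matrix(FALSE, nr + 2L, nc + 2L)
      P[2:(nr + 1L), 2:(nc + 1L)] <- B
      ri <- 2:(nr + 1L); ci <- 2:(nc + 1L)
      p2 <- P[ri - 1L, ci]; p3 <- P[ri - 1L, ci + 1L]; p4 <- P[ri, ci + 1L]
      p5 <- P[ri + 1L, ci + 1L]; p6 <- P[ri + 1L, ci]; p7 <- P[ri + 1L, ci - 1L]
      p8 <- P[ri, ci - 1L]; p9 <- P[ri - 1L, ci - 1L]
      C <- (!p2 & (p3 | p4)) + (!p4 & (p5 | p6)) +
        (!p6 & (p7 | p8)) + (!p8 & (p9 | p2))
      N1 <- (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8)
      N2 <- (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9)
      N <- pmin(N1, N2)
      m <- if (phase == 1L) ((p6 | p7 | !p9) & p8) else ((p2 | p3 | !p5) & p4)
      cond <- B & C == 1 & N >= 2 & N <= 3 & !m
      if (any(cond)) { B[cond] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  B
}

# 8-connected component labels for a logical matrix; returns integer matrix
label8 <- function(B) {
  lab <- matrix(0L, nrow(B), ncol(B))
  idx <- which(B)
  if (!length(idx)) return(lab)
  nr <- nrow(B)
  nxt <- 0L
  for (start in idx) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- ((cur - 1L) %% nr) + 1L
      c_ <- ((cur - 1L) %/% nr) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        r2 <- r + dr; c2 <- c_ + dc
        if (r2 < 1L || c2 < 1L || r2 > nr || c2 > ncol(B)) next
        j <- r2 + (c2 - 1L) * nr
        if (B[j] && lab[j] == 0L) { lab[j] <- nxt; queue <- c(queue, j) }
      }
    }
  }
  lab
}

# reduce a thinned skeleton to a minimal 8-connected chain: drop pixels
# whose two neighbors are themselves adjacent (staircase fillers, which
# create spurious junctions and inflate chain-code lengths)
remove_redundant <- function(skel) {
  nr <- nrow(skel); nc <- ncol(skel)
  repeat {
    changed <- FALSE
    for (j in which(skel)) {
      r <- ((j - 1L) %% nr) + 1L
      c_ <- ((j - 1L) %/% nr) + 1L
      nbs <- integer(0)
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        r2 <- r + dr; c2 <- c_ + dc
        if (r2 < 1L || c2 < 1L || r2 > nr || c2 > nc) next
        j2 <- r2 + (c2 - 1L) * nr
        if (skel[j2]) nbs <- c(nbs, j2)
      }
      if (length(nbs) == 2L) {
        ra <- ((nbs - 1L) %% nr) + 1L
        ca <- ((nbs - 1L) %/% nr) + 1L
        if (abs(ra[1] - ra[2]) <= 1L && abs(ca[1] - ca[2]) <= 1L) {
          skel[j] <- FALSE
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  skel
}

# remove skeleton spurs: endpoint branches of at most max_len pixels that
# terminate at a junction (thinning artifacts on a noisy stroke outline)
prune_spurs <- function(skel, max_len = 4L) {
  nr <- nrow(skel); nc <- ncol(skel)
  neighbor_idx <- function(j) {
    r <- ((j - 1L) %% nr) + 1L
    c_ <- ((j - 1L) %/% nr) + 1L
    out <- integer(0)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      r2 <- r + dr; c2 <- c_ + dc
      if (r2 < 1L || c2 < 1L || r2 > nr || c2 > nc) next
      j2 <- r2 + (c2 - 1L) * nr
      if (skel[j2]) out <- c(out, j2)
    }
    out
  }
  repeat {
    deg <- matrix(0L, nr, nc)
    on <- which(skel)
    for (j in on) deg[j] <- length(neighbor_idx(j))
    removed <- FALSE
    for (j in on[deg[on] == 1L]) {
      if (!skel[j]) next
      path <- j
      cur <- j
      prev <- -1L
      hit_junction <- FALSE
      for (step in seq_len(max_len)) {
        nb <- setdiff(neighbor_idx(cur), prev)
        if (!length(nb)) break
        if (length(nb) > 1L || deg[nb[1]] >= 3L) { hit_junction <- TRUE; break }
        prev <- cur
        cur <- nb[1]
        path <- c(path, cur)
      }
      if (hit_junction && length(path) <= max_len) {
        skel[path] <- FALSE
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  skel
}

# corner-corrected chain length (px) of an ordered 8-connected path
chain_length_px <- function(rows, cols) {
  if (length(rows) < 2L) return(0)
  dr <- diff(rows); dc <- diff(cols)
  diag_step <- abs(dr) == 1L & abs(dc) == 1L
  n_even <- sum(!diag_step)
  n_odd <- sum(diag_step)
  dirs <- atan2(dr, dc)
  n_corner <- sum(abs(diff(dirs)) > 1e-9)
  0.980 * n_even + 1.406 * n_odd - 0.091 * n_corner
}

# order a branch-free skeleton component from an endpoint; NULL for cycles
order_path <- function(rows, cols) {
  n <- length(rows)
  if (n == 1L) return(list(rows = rows, cols = cols))
  adj <- lapply(seq_len(n), function(i)
    which(abs(rows - rows[i]) <= 1L & abs(cols - cols[i]) <= 1L &
          !(rows == rows[i] & cols == cols[i])))
  deg <- lengths(adj)
  ends <- which(deg == 1L)
  if (!length(ends)) return(NULL)
  ord <- integer(n)
  ord[1] <- ends[1]
  visited <- logical(n)
  visited[ends[1]] <- TRUE
  for (k in 2:n) {
    nb <- adj[[ord[k - 1L]]]
    nb <- nb[!visited[nb]]
    if (!length(nb)) return(list(rows = rows[ord[1:(k - 1L)]],
                                 cols = cols[ord[1:(k - 1L)]]))
    # prefer axial continuation to avoid zig-zag ordering at corners
    ord[k] <- nb[1]
    visited[nb[1]] <- TRUE
  }
  list(rows = rows[ord], cols = cols[ord])
}

#' Detect and measure Z-lines in a region of interest
#'
#' Hysteresis thresholding of the background-normalized ROI, Guo-Hall
#' skeletonization, decomposition into branch-free paths at skeleton branch
#' points, and corner-corrected chain-code length per path. Paths touching
#' the ROI border are excluded (their lengths are censored). An
#' `end_correction_px` term compensates the one-pixel endpoint retreat of
#' thinning on flat-capped strokes.
#'
#' @param roi Grayscale ROI matrix.
#' @param pixel_size_um Micrometers per pixel.
#' @param high_k,low_k Hysteresis thresholds in robust SD units above the
#'   background median.
#' @param min_length_px Discard skeleton paths shorter than this many
#'   pixels.
#' @param end_correction_px Length added per detected path (px).
#' @return Numeric vector of segment lengths, micrometers (possibly empty).
#' @export
detect_zlines <- function(roi, pixel_size_um, high_k = 6, low_k = 2.5,
                          min_length_px = 5, end_correction_px = 1) {
  bg <- stats::median(roi)
  s <- stats::mad(roi)
  if (s <= 0) s <- stats::sd(roi)
  if (is.na(s) || s <= 0) return(numeric(0))
  low <- roi > bg + low_k * s
  high <- roi > bg + high_k * s
  if (!any(high)) return(numeric(0))
  lab_low <- label8(low)
  keep <- unique(lab_low[high])
  mask <- matrix(lab_low %in% keep & lab_low > 0, nrow(roi), ncol(roi))
  skel <- gh_thin(mask)
  if (!any(skel)) return(numeric(0))
  skel <- remove_redundant(skel)
  skel <- prune_spurs(skel, max_len = 4L)
  skel <- remove_redundant(skel)
  if (!any(skel)) return(numeric(0))

  # branch-point decomposition: drop pixels with >2 skeleton neighbors
  P <- matrix(FALSE, nrow(skel) + 2L, ncol(skel) + 2L)
  P[2:(nrow(skel) + 1L), 2:(ncol(skel) + 1L)] <- skel
  ri <- 2:(nrow(skel) + 1L); ci <- 2:(ncol(skel) + 1L)
  nb <- P[ri - 1L, ci] + P[ri - 1L, ci + 1L] + P[ri, ci + 1L] +
    P[ri + 1L, ci + 1L] + P[ri + 1L, ci] + P[ri + 1L, ci - 1L] +
    P[ri, ci - 1L] + P[ri - 1L, ci - 1L]
  segs <- skel & nb <= 2L
  lab <- label8(segs)
  out <- numeric(0)
  for (k in seq_len(max(lab))) {
    idx <- which(lab == k, arr.ind = TRUE)
    if (nrow(idx) < 2L) next
    if (any(idx[, 1] <= 1L | idx[, 2] <= 1L |
            idx[, 1] >= nrow(roi) | idx[, 2] >= ncol(roi))) next
    path <- order_path(idx[, 1], idx[, 2])
    if (is.null(path)) next
    len <- chain_length_px(path$rows, path$cols) + end_correction_px
    if (len >= min_length_px) out <- c(out, len * pixel_size_um)
  }
  out
}

#' Pooled Z-line length summaries per group
#'
#' @param lengths_by_group Named list of numeric vectors of segment lengths
#'   (micrometers), one element per group.
#' @return data.frame with group, n, pooled mean, SD, and 95% CI half-width.
#' @export
summarize_lengths <- function(lengths_by_group) {
  stopifnot(is.list(lengths_by_group), length(lengths_by_group) >= 1)
  out <- lapply(names(lengths_by_group), function(g) {
    x <- lengths_by_group[[g]]
    if (length(x) < 2L) stop(sprintf("group '%s' has fewer than 2 segments", g))
    ci <- ci95(x)
    data.frame(group = g, n = length(x), mean_um = ci$mean,
               sd_um = stats::sd(x), ci95_um = ci$half_width,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
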