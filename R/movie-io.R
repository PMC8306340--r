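#' Write a mapping movie as multi-page TIFF plus JSON metadata
#'
#' Frames are stored in acquisition order as 16-bit grayscale pages;
#' intensities are camera counts in `[0, 65535]`. Acquisition metadata goes
#' to a JSON sidecar with keys `frame_interval_ms`, `pixel_pitch_mm`,
#' `stimulus_times_ms`, `cycle_length_ms`, `channel`, `frames`, `rows`,
#' `cols`.
#'
#' @param movie A [mapping_movie()].
#' @param path Output TIFF path.
#' @param metadata_path Output JSON path (default: `path` with `.json`).
#' @return Invisibly, the two paths.
#' @export
write_movie <- function(movie, path, metadata_path = NULL) {
  if (is.null(metadata_path)) metadata_path <- sub("\\.tiff?$", ".json", path)
  if (metadata_path == path) metadata_path <- paste0(path, ".json")
  d <- dim(movie$data)
  counts <- pmin(pmax(round(movie$data), 0), 65535)
  pages <- lapply(seq_len(d[1]), function(f) counts[f, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- list(frame_interval_ms = movie$frame_interval,
               pixel_pitch_mm = movie$pixel_pitch,
               stimulus_times_ms = movie$stimulus_times,
               cycle_length_ms = movie$cycle_length,
               channel = movie$channel,
               frames = d[1], rows = d[2], cols = d[3])
  jsonlite::write_json(meta, metadata_path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(c(path, metadata_path))
}

read_metadata <- function(metadata_path, required) {
  meta <- jsonlite::read_json(metadata_path, simplifyVector = TRUE)
  for (key in required)
    if (is.null(meta[[key]]) || all(is.na(meta[[key]])) && key != "cycle_length_ms")
      stop(sprintf("metadata is missing required field '%s'", key))
  meta
}

#' Read a mapping movie
#'
#' Reads a multi-page 16-bit TIFF (or a camera-native raw binary dump of
#' little-endian uint16 frames, row-major within each frame) with its JSON
#' metadata sidecar. Intensities round-trip bit-exactly for integer counts
#' in `[0, 65535]`.
#'
#' @param path TIFF or raw binary path.
#' @param metadata_path JSON metadata path.
#' @param format `"tiff"` or `"raw"`. Raw requires `frames`, `rows`,
#'   `cols` in the metadata.
#' @return A [mapping_movie()].
#' @export
read_movie <- function(path, metadata_path, format = c("tiff", "raw")) {
  format <- match.arg(format)
  meta <- read_metadata(metadata_path,
                        c("frame_interval_ms", "pixel_pitch_mm"))
  if (format == "tiff") {
    pages <- tiff::readTIFF(path, all = TRUE)
    Fn <- length(pages)
    if (!is.null(meta$frames) && meta$frames != Fn)
      stop(sprintf("frame-count mismatch: metadata field 'frames' says %d, file has %d",
                   meta$frames, Fn))
    d <- dim(pages[[1]])
    data <- array(0, c(Fn, d[1], d[2]))
    for (f in seq_len(Fn)) data[f, , ] <- round(pages[[f]] * 65535)
  } else {
    for (key in c("frames", "rows", "cols"))
      if (is.null(meta[[key]]))
        stop(sprintf("metadata is missing required field '%s'", key))
    n <- meta$frames * meta$rows * meta$cols
    v <- readBin(path, what = "integer", n = n, size = 2L, signed = FALSE,
                 endian = "little")
    if (length(v) != n)
      stop(sprintf("frame-count mismatch: expected %d values, file has %d",
                   n, length(v)))
    # frame-major, row-major within frame
    data <- aperm(array(v, c(meta$cols, meta$rows, meta$frames)), c(3, 2, 1))
  }
  stim <- meta$stimulus_times_ms
  if (is.null(stim)) stim <- numeric(0)
  cl <- if (is.null(meta$cycle_length_ms)) NA_real_ else as.numeric(meta$cycle_length_ms)
  ch <- if (is.null(meta$channel)) "voltage" else meta$channel
  mapping_movie(data, frame_interval = as.numeric(meta$frame_interval_ms),
                pixel_pitch = as.numeric(meta$pixel_pitch_mm),
                stimulus_times = as.numeric(stim), cycle_length = cl,
                channel = ch)
}

#' Write a raw binary movie dump
#'
#' Little-endian uint16, frame-major, row-major within each frame, with the
#' same JSON sidecar as [write_movie()].
#'
#' @inheritParams write_movie
#' @export
write_movie_raw <- function(movie, path, metadata_path = NULL) {
  if (is.null(metadata_path)) metadata_path <- paste0(path, ".json")
  counts <- pmin(pmax(round(movie$data), 0), 65535)
  v <- as.integer(aperm(counts, c(3, 2, 1)))
  writeBin(v, path, size = 2L, endian = "little")
  d <- dim(movie$data)
  meta <- list(frame_interval_ms = movie$frame_interval,
               pixel_pitch_mm = movie$pixel_pitch,
               stimulus_times_ms = movie$stimulus_times,
               cycle_length_ms = movie$cycle_length,
               channel = movie$channel,
               frames = d[1], rows = d[2], cols = d[3])
  jsonlite::write_json(meta, metadata_path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(c(path, metadata_path))
}

#' Isochrone contours of an activation map
#'
#' Equal-activation-time contour lines at a fixed spacing (5 ms in the
#' conventional rendering), returned as coordinate paths in pixel units.
#'
#' @param act Activation-time matrix, ms.
#' @param interval Isochrone spacing, ms.
#' @return A list of data.frames with `level`, `row`, `col`.
#' @export
isochrones <- function(act, interval = 5) {
  rng <- range(act, na.rm = TRUE)
  levels <- seq(ceiling(rng[1] / interval) * interval, rng[2], by = interval)
  if (!length(levels)) return(list())
  z <- act
  z[!is.finite(z)] <- NA
  cl <- grDevices::contourLines(x = seq_len(nrow(act)), y = seq_len(ncol(act)),
                                z = z, levels = levels)
  lapply(cl, function(l) data.frame(level = l$level, row = l$x, col = l$y))
}

#' Write metric maps as CSV tables and rendered PNGs
#'
#' One CSV per metric with 0-based `row`, `col`, `value` in row-major
#' order, invalid pixels omitted; one PNG per metric, with a 5 ms isochrone
#' overlay for any map named `activation_time`.
#'
#' @param maps Named list of metric matrices on a common grid.
#' @param mask Logical validity matrix on the same grid.
#' @param out_dir Output directory (created if needed).
#' @param isochrone_interval Isochrone spacing, ms.
#' @return Invisibly, the written file paths.
#' @export
write_maps <- function(maps, mask, out_dir, isochrone_interval = 5) {
  stopifnot(is.list(maps), length(maps) >= 1)
  d <- dim(maps[[1]])
  for (m in maps) if (!identical(dim(m), d)) stop("maps are on different grids")
  if (!identical(dim(mask), d)) stop("mask grid does not match the maps")
  if (!any(mask)) stop("empty mask: nothing to write")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (name in names(maps)) {
    m <- maps[[name]]
    sel <- which(mask & is.finite(m), arr.ind = TRUE)
    df <- data.frame(row = sel[, 1] - 1L, col = sel[, 2] - 1L,
                     value = m[sel])
    df <- df[order(df$row, df$col), ]
    csv <- file.path(out_dir, paste0(name, ".csv"))
    utils::write.csv(df, csv, row.names = FALSE)
    png_path <- file.path(out_dir, paste0(name, ".png"))
    grDevices::png(png_path, width = 480, height = 480)
    op <- graphics::par(mar = c(2, 2, 2, 1))
    mm <- m
    mm[!mask] <- NA
    graphics::image(seq_len(d[2]), seq_len(d[1]), t(mm)[, d[1]:1, drop = FALSE],
                    col = grDevices::hcl.colors(64, "viridis"),
                    xlab = "", ylab = "", main = name, useRaster = TRUE)
    if (name == "activation_time") {
      iso <- isochrones(mm, isochrone_interval)
      for (l in iso)
        graphics::lines(l$col, d[1] + 1 - l$row, col = "white", lwd = 1.2)
    }
    graphics::par(op)
    grDevices::dev.off()
    paths <- c(paths, csv, png_path)
  }
  invisible(paths)
}
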