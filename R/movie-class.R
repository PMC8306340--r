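#' Mapping movie container
#'
#' A fluorescence movie from a mapping camera plus its acquisition metadata.
#' Data are stored as a `frames x rows x cols` array of nonnegative
#' intensities (camera counts). Time 0 is the first frame; all times are in
#' ms; pixel coordinates are (row, col), row-major.
#'
#' @param data Numeric array, `frames x rows x cols`.
#' @param frame_interval Frame interval, ms.
#' @param pixel_pitch Pixel pitch, mm.
#' @param stimulus_times Pacing stimulus times, ms (may be empty for
#'   spontaneous recordings; must be strictly increasing and inside the
#'   movie).
#' @param cycle_length Pacing cycle length, ms (NA for spontaneous).
#' @param channel `"voltage"` or `"calcium"`.
#' @return An object of class `mapping_movie`.
#' @export
mapping_movie <- function(data, frame_interval, pixel_pitch,
                          stimulus_times = numeric(0), cycle_length = NA_real_,
                          channel = c("voltage", "calcium")) {
  channel <- match.arg(channel)
  if (length(dim(data)) != 3L) stop("data must be a frames x rows x cols array")
  if (dim(data)[1] < 2L) stop("movie must have at least 2 frames")
  if (!(frame_interval > 0)) stop("frame_interval must be > 0")
  if (!(pixel_pitch > 0)) stop("pixel_pitch must be > 0")
  dur <- (dim(data)[1] - 1L) * frame_interval
  if (length(stimulus_times)) {
    if (is.unsorted(stimulus_times, strictly = TRUE))
      stop("stimulus_times must be strictly increasing")
    if (min(stimulus_times) < 0 || max(stimulus_times) > dur)
      stop("stimulus_times must lie within the movie duration")
  }
  structure(
    list(data = data, frame_interval = frame_interval,
         pixel_pitch = pixel_pitch, stimulus_times = as.numeric(stimulus_times),
         cycle_length = cycle_length, channel = channel),
    class = "mapping_movie")
}

#' @export
print.mapping_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<mapping_movie> %s, %d frames x %d x %d px, dt=%g ms, pitch=%g mm\n",
              x$channel, d[1], d[2], d[3], x$frame_interval, x$pixel_pitch))
  cat(sprintf("  duration %g ms, %d stimuli%s\n",
              (d[1] - 1) * x$frame_interval, length(x$stimulus_times),
              if (is.na(x$cycle_length)) "" else sprintf(", cycle %g ms", x$cycle_length)))
  invisible(x)
}

#' Frame times of a movie
#' @param movie A [mapping_movie()].
#' @return Numeric vector of frame times, ms.
#' @export
frame_times <- function(movie) {
  (seq_len(dim(movie$data)[1]) - 1) * movie$frame_interval
}

# Movie data as a frames x npix matrix; column j is pixel
# (row = (j-1) %% rows + 1, col = (j-1) %/% rows + 1).
trace_matrix <- function(movie) {
  d <- dim(movie$data)
  matrix(movie$data, nrow = d[1])
}

n_pixels <- function(movie) prod(dim(movie$data)[2:3])

grid_dim <- function(movie) dim(movie$data)[2:3]

# moving average with edge-shrinking window, columnwise on a matrix
ma_smooth <- function(x, width) {
  if (width <= 1L) return(x)
  if (is.matrix(x)) return(apply(x, 2L, ma_smooth, width = width))
  n <- length(x)
  half <- width %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
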