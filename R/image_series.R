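#' Multi-channel time-lapse image series
#'
#' Container for a 2D+t (TIRF-like) or 3D+t (light-sheet-like) multi-channel
#' acquisition together with its physical calibration. Pixel data are stored
#' as a numeric array with dimensions \code{T x C x Y x X} (\code{tirf2d}) or
#' \code{T x C x Z x Y x X} (\code{llsm3d}). Frame times are
#' \code{(t - 1) * frame_interval} seconds, with time zero at the first
#' acquired frame. Pixel coordinates throughout the package are 1-based pixel
#' centers in \code{(y, x)} / \code{(z, y, x)} order.
#'
#' @param data numeric array, \code{T x C x Y x X} or \code{T x C x Z x Y x X}.
#' @param pixel_pitch lateral pixel size in micrometers (isotropic in x/y).
#' @param frame_interval time between frames in seconds.
#' @param z_step axial step in micrometers; required for 5-d data.
#' @param channels character vector of channel names, one per channel.
#' @return An object of class \code{image_series}.
#' @examples
#' a <- array(0, dim = c(3, 2, 16, 16))
#' s <- image_series(a, pixel_pitch = 0.1, frame_interval = 1.5)
#' frame_times(s)
#' @export
image_series <- function(data, pixel_pitch, frame_interval, z_step = NULL,
                         channels = NULL) {
  d <- dim(data)
  if (!(length(d) %in% c(4L, 5L)))
    stop("data must be a T x C x Y x X or T x C x Z x Y x X array")
  mode <- if (length(d) == 4L) "tirf2d" else "llsm3d"
  if (mode == "llsm3d" && is.null(z_step))
    stop("z_step is required for 3D+t data")
  if (!is.numeric(pixel_pitch) || pixel_pitch <= 0)
    stop("pixel_pitch must be positive")
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be positive")
  if (is.null(channels)) channels <- paste0("ch", seq_len(d[2]))
  if (length(channels) != d[2]) stop("one channel name per channel required")
  structure(list(data = data, mode = mode, pixel_pitch = pixel_pitch,
                 z_step = z_step, frame_interval = frame_interval,
                 channels = channels),
            class = "image_series")
}

#' @export
print.image_series <- function(x, ...) {
  d <- dim(x$data)
  cat("<image_series> mode:", x$mode, "| frames:", d[1],
      "| channels:", paste(x$channels, collapse = ","),
      "| field:", paste(d[-(1:2)], collapse = "x"),
      sprintf("| pitch %.3g um, interval %.3g s\n",
              x$pixel_pitch, x$frame_interval))
  invisible(x)
}

#' Number of frames of an image series
#' @param series an \code{image_series}.
#' @return integer frame count.
#' @export
n_frames <- function(series) dim(series$data)[1]

#' Acquisition times of each frame
#' @param series an \code{image_series}.
#' @return numeric vector of times in seconds, starting at 0.
#' @export
frame_times <- function(series) {
  (seq_len(n_frames(series)) - 1) * series$frame_interval
}

#' Physical sample spacing per spatial axis
#' @param series an \code{image_series}.
#' @return micrometers per pixel in \code{(y, x)} or \code{(z, y, x)} order.
#' @export
series_spacing <- function(series) {
  if (series$mode == "tirf2d") c(series$pixel_pitch, series$pixel_pitch)
  else c(series$z_step, series$pixel_pitch, series$pixel_pitch)
}

#' Extract one spatial frame
#' @param series an \code{image_series}.
#' @param t frame index (1-based).
#' @param channel channel index or name.
#' @return a \code{Y x X} matrix or \code{Z x Y x X} array.
#' @export
get_frame <- function(series, t, channel) {
  if (is.character(channel)) channel <- match(channel, series$channels)
  d <- dim(series$data)
  if (t < 1 || t > d[1]) stop("frame index out of range")
  if (is.na(channel) || channel < 1 || channel > d[2])
    stop("unknown channel")
  if (series$mode == "tirf2d") {
    array(series$data[t, channel, , ], dim = d[3:4])
  } else {
    array(series$data[t, channel, , , ], dim = d[3:5])
  }
}
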