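#' Write an image series as multi-page TIFF with a metadata sidecar
#'
#' Pages are written in T-major order (for each frame: all channels, and in
#' 3D all z planes per channel), i.e. axis order TCYX or TZCYX as 32-bit
#' float. TIFF float storage is reliable in [0, 1], so intensities are
#' scaled by the series maximum and the scale factor is recorded, together
#' with pixel pitch, z step, frame interval and channel names, in a JSON
#' sidecar (\code{<path>.json}).
#'
#' @param series an \code{image_series}.
#' @param path output TIFF path.
#' @return (invisibly) the sidecar path.
#' @export
write_image_series <- function(series, path) {
  d <- dim(series$data)
  scale <- max(series$data, 1e-12)
  pages <- list()
  if (series$mode == "tirf2d") {
    for (t in seq_len(d[1])) for (ch in seq_len(d[2])) {
      pages[[length(pages) + 1L]] <-
        array(series$data[t, ch, , ], dim = d[3:4]) / scale
    }
  } else {
    for (t in seq_len(d[1])) for (z in seq_len(d[3])) for (ch in seq_len(d[2])) {
      pages[[length(pages) + 1L]] <-
        array(series$data[t, ch, z, , ], dim = d[4:5]) / scale
    }
  }
  meta <- list(mode = series$mode, axis_order = if (series$mode == "tirf2d")
                 "TCYX" else "TZCYX",
               shape = d, pixel_pitch_um = series$pixel_pitch,
               z_step_um = series$z_step,
               frame_interval_s = series$frame_interval,
               channels = series$channels, intensity_scale = scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(sidecar)
}

#' Read an image series written by \code{write_image_series}
#'
#' Physical metadata are taken from the JSON sidecar (or can be overridden
#' explicitly); missing metadata is an error naming the missing field, so a
#' series is never silently uncalibrated.
#'
#' @param path TIFF path.
#' @param pixel_pitch,frame_interval,z_step,channels optional overrides for
#'   (or replacements of) sidecar metadata.
#' @param axis_order expected axis order (\code{"TCYX"} or \code{"TZCYX"});
#'   an explicit declaration that conflicts with the file is an error.
#' @return an \code{image_series}.
#' @export
read_image_series <- function(path, pixel_pitch = NULL,
                              frame_interval = NULL, z_step = NULL,
                              channels = NULL, axis_order = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar,
                                                        simplifyVector = TRUE)
          else list()
  pick <- function(override, field) {
    if (!is.null(override)) return(override)
    if (!is.null(meta[[field]])) return(meta[[field]])
    stop("missing metadata: ", field,
         " (no sidecar value and no explicit argument)")
  }
  pixel_pitch <- pick(pixel_pitch, "pixel_pitch_um")
  frame_interval <- pick(frame_interval, "frame_interval_s")
  file_order <- if (!is.null(meta$axis_order)) meta$axis_order else axis_order
  if (is.null(file_order)) stop("missing metadata: axis_order")
  if (!is.null(axis_order) && axis_order != file_order)
    stop("axis order mismatch: file is ", file_order,
         ", declared ", axis_order)
  if (file_order == "TZCYX") z_step <- pick(z_step, "z_step_um")
  scale <- if (!is.null(meta$intensity_scale)) meta$intensity_scale else 1
  pages <- tiff::readTIFF(path, all = TRUE)
  shape <- if (!is.null(meta$shape)) as.integer(meta$shape) else NULL
  if (file_order == "TCYX") {
    if (is.null(shape)) {
      nc <- if (!is.null(channels)) length(channels) else
        stop("missing metadata: shape or channels")
      shape <- c(length(pages) / nc, nc, dim(pages[[1]]))
    }
    data <- array(0, dim = shape)
    k <- 0L
    for (t in seq_len(shape[1])) for (ch in seq_len(shape[2])) {
      k <- k + 1L
      data[t, ch, , ] <- pages[[k]] * scale
    }
  } else {
    if (is.null(shape)) stop("missing metadata: shape")
    data <- array(0, dim = shape)
    k <- 0L
    for (t in seq_len(shape[1])) for (z in seq_len(shape[3]))
      for (ch in seq_len(shape[2])) {
        k <- k + 1L
        data[t, ch, z, , ] <- pages[[k]] * scale
      }
  }
  chn <- if (!is.null(channels)) channels else meta$channels
  image_series(data, pixel_pitch = pixel_pitch,
               frame_interval = frame_interval, z_step = z_step,
               channels = chn)
}

#' Write a stack of frames (label images, distance fields) as TIFF
#'
#' Generic multi-page writer for per-frame arrays such as label images or
#' distance fields; values are scaled to [0, 1] with the scale recorded in
#' a JSON sidecar. 3-d frames are written plane by plane.
#'
#' @param frames list of numeric arrays, one per frame, identical shapes.
#' @param path output TIFF path.
#' @return (invisibly) the sidecar path.
#' @export
write_frames_tiff <- function(frames, path) {
  finite_max <- max(vapply(frames, function(f)
    max(c(f[is.finite(f)], 0)), numeric(1)), 1e-12)
  pages <- list()
  for (f in frames) {
    f[!is.finite(f)] <- finite_max
    if (length(dim(f)) == 3) {
      for (z in seq_len(dim(f)[1]))
        pages[[length(pages) + 1L]] <- array(f[z, , ], dim = dim(f)[2:3]) /
          finite_max
    } else {
      pages[[length(pages) + 1L]] <- f / finite_max
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(n_frames = length(frames), frame_shape = dim(frames[[1]]),
               value_scale = finite_max)
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Write a simulation to disk
#'
#' Images as multi-page TIFF with JSON sidecar; ground truth as CSV (one
#' row per vesicle-frame plus a per-vesicle summary, cluster table and
#' flare table).
#'
#' @param sim a \code{simulation}.
#' @param dir output directory (created if needed).
#' @return (invisibly) the directory.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_image_series(sim$images, file.path(dir, "images.tif"))
  utils::write.csv(sim$truth$vesicle_frames,
                   file.path(dir, "truth_vesicle_frames.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$truth$vesicles,
                   file.path(dir, "truth_vesicles.csv"), row.names = FALSE)
  utils::write.csv(sim$truth$clusters,
                   file.path(dir, "truth_clusters.csv"), row.names = FALSE)
  utils::write.csv(sim$truth$flares,
                   file.path(dir, "truth_flares.csv"), row.names = FALSE)
  invisible(dir)
}
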