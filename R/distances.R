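#' Distance field from microcluster surfaces
#'
#' Euclidean distance transform of the background of the cluster label image
#' with anisotropic physical spacing: each pixel holds the distance in
#' micrometers to the nearest cluster pixel, and cluster pixels themselves
#' hold zero. When no cluster pixel exists the field is +Inf everywhere and
#' a warning is recorded on the result (attribute \code{"warning"}).
#'
#' @param cluster_labels integer label array (or logical mask), 2-d or 3-d.
#' @param spacing micrometers per sample per axis, in array axis order.
#' @return numeric array of distances (micrometers), same shape.
#' @export
cluster_distance_field <- function(cluster_labels, spacing) {
  d <- dim(cluster_labels)
  if (length(spacing) != length(d))
    stop("spacing must have one entry per axis")
  if (any(spacing <= 0)) stop("spacing must be positive per axis")
  mask <- cluster_labels > 0
  if (!any(mask)) {
    field <- array(Inf, dim = d)
    attr(field, "warning") <- "no cluster pixels; distance field is infinite"
    warning("no cluster pixels; distance field is infinite")
    return(field)
  }
  sq <- edt_squared_cpp(as.numeric(mask), as.integer(d), as.numeric(spacing))
  array(sqrt(sq), dim = d)
}

#' Per-frame vesicle-to-cluster distances along a track
#'
#' Samples the cluster distance field at the (rounded) vesicle centroid for
#' every observed frame of the track.
#'
#' @param track a vesicle \code{track}.
#' @param fields_by_frame list of distance fields indexed by frame; every
#'   observed frame of the track must be present.
#' @param frame_times acquisition time (seconds) of each frame.
#' @return data.frame of class \code{distance_series}: \code{track_id},
#'   \code{frame}, \code{time_s}, \code{distance_um}.
#' @export
vesicle_distance_series <- function(track, fields_by_frame, frame_times) {
  n <- track_lifetime(track)
  dist <- numeric(n)
  for (i in seq_len(n)) {
    f <- track$frame[i]
    if (f > length(fields_by_frame) || is.null(fields_by_frame[[f]]))
      stop("no distance field for frame ", f)
    field <- fields_by_frame[[f]]
    d <- dim(field)
    pos <- round(track$centroid[i, ])
    if (any(pos < 1) || any(pos > d))
      stop("vesicle centroid outside the field at frame ", f)
    lin <- pos[1]
    if (length(d) >= 2) lin <- lin + (pos[2] - 1) * d[1]
    if (length(d) == 3) lin <- lin + (pos[3] - 1) * d[1] * d[2]
    dist[i] <- field[lin]
  }
  out <- data.frame(track_id = track$id, frame = track$frame,
                    time_s = frame_times[track$frame], distance_um = dist)
  class(out) <- c("distance_series", "data.frame")
  out
}

#' Earliest vesicle-microcluster contact time
#'
#' Minimum, over a set of vesicle distance series, of the earliest frame
#' time at which the distance falls to \code{contact_radius} or less.
#'
#' @param series_set list of \code{distance_series} (or a single one).
#' @param contact_radius contact cutoff in micrometers; by default one xy
#'   pixel pitch should be supplied by the caller.
#' @return earliest contact time in seconds, or \code{NA} when no vesicle
#'   ever comes within the radius.
#' @export
first_contact_time <- function(series_set, contact_radius) {
  if (is.data.frame(series_set)) series_set <- list(series_set)
  if (!length(series_set)) stop("empty set of distance series")
  best <- Inf
  for (s in series_set) {
    hit <- s$time_s[s$distance_um <= contact_radius]
    if (length(hit)) best <- min(best, min(hit))
  }
  if (is.infinite(best)) NA_real_ else best
}

#' Time of appearance of a channel's signal
#'
#' The time of the first frame containing at least one object that persists:
#' objects are linked into tracks (tracking defaults) and a frame qualifies
#' when some track is observed in \code{min_persistence} consecutive frames
#' starting there or earlier. Single-frame blips are thereby ignored.
#'
#' @param objects_by_frame \code{detection_series} or list of
#'   \code{labeled_objects}.
#' @param frame_times acquisition times in seconds.
#' @param min_persistence required consecutive observations (>= 1).
#' @param max_disp,max_gap linking parameters.
#' @return appearance time in seconds, or \code{NA} when no object persists.
#' @export
appearance_time <- function(objects_by_frame, frame_times,
                            min_persistence = 3, max_disp = 5, max_gap = 2) {
  if (min_persistence < 1) stop("min_persistence must be >= 1")
  tracks <- link_tracks(objects_by_frame, max_disp = max_disp,
                        max_gap = max_gap)
  best <- Inf
  for (tr in tracks) {
    f <- tr$frame
    if (length(f) < min_persistence) next
    # starts of runs of consecutive observed frames of sufficient length
    i <- 1L
    while (i <= length(f)) {
      j <- i
      while (j < length(f) && f[j + 1L] == f[j] + 1L) j <- j + 1L
      if (j - i + 1L >= min_persistence) best <- min(best, f[i])
      i <- j + 1L
    }
  }
  if (is.infinite(best)) NA_real_ else frame_times[best]
}
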