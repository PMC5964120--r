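#' Relative fluorescence intensity of both channels within a vesicle
#'
#' For every observed frame of a vesicle track, sums each channel's raw
#' intensity over the vesicle's segmentation mask and normalizes each
#' channel's series by its own mean over the track, giving relative
#' fluorescence intensity (RFI) series with mean exactly 1.
#'
#' @param track a vesicle \code{track}.
#' @param series the \code{image_series} the track was detected in.
#' @param vesicles_by_frame \code{detection_series} for the vesicle channel
#'   supplying the masks; every observed frame must have the track's object.
#' @return data.frame of class \code{rfi_series}: \code{frame}, plus one
#'   RFI column per channel (named after the series channels).
#' @export
object_rfi_series <- function(track, series, vesicles_by_frame) {
  ve <- if (inherits(vesicles_by_frame, "detection_series"))
    vesicles_by_frame$frames else vesicles_by_frame
  n <- track_lifetime(track)
  nc <- length(series$channels)
  sums <- matrix(0, n, nc)
  for (i in seq_len(n)) {
    f <- track$frame[i]
    mask <- ve[[f]]$labels == track$label[i]
    if (!any(mask)) stop("empty vesicle mask at frame ", f)
    for (ch in seq_len(nc)) {
      sums[i, ch] <- sum(get_frame(series, f, ch)[mask])
    }
  }
  rfi <- sweep(sums, 2, colMeans(sums), "/")
  out <- data.frame(frame = track$frame)
  for (ch in seq_len(nc)) out[[series$channels[ch]]] <- rfi[, ch]
  class(out) <- c("rfi_series", "data.frame")
  attr(out, "track_id") <- track$id
  out
}

#' Detect coincident two-channel intensity flares
#'
#' Flags frames whose RFI exceeds a robust baseline (median + k * MAD, MAD
#' scaled to the SD equivalent) in each channel, then reports flare events:
#' runs of at least \code{min_frames} frames that are flagged in one channel
#' while the other channel is also flagged within \code{coincidence} frames.
#' A robust baseline is used because the flares themselves would inflate a
#' mean/SD baseline.
#'
#' @param rfi an \code{rfi_series} with exactly two channel columns.
#' @param k baseline multiplier (> 0).
#' @param min_frames minimum run length of a flare (>= 1).
#' @param coincidence cross-channel slack in frames.
#' @return data.frame of class \code{flare_events}: \code{start_frame},
#'   \code{duration}, and per-channel peak RFI within the event.
#' @export
detect_flares <- function(rfi, k = 3, min_frames = 3, coincidence = 1) {
  if (k <= 0) stop("k must be positive")
  if (min_frames < 1) stop("min_frames must be >= 1")
  chans <- setdiff(names(rfi), "frame")
  if (length(chans) != 2) stop("rfi must contain exactly two channels")
  n <- nrow(rfi)
  if (n < 2 * min_frames)
    stop("track too short for flare detection (need >= 2*min_frames frames)")
  flag <- sapply(chans, function(ch) {
    x <- rfi[[ch]]
    base <- stats::median(x)
    s <- stats::mad(x) # scaled to SD equivalent (constant 1.4826)
    if (s == 0) return(rep(FALSE, n))
    x > base + k * s
  })
  near <- function(v, w) { # any flag within +/- w positions
    out <- v
    if (w > 0) for (o in seq_len(w)) {
      out <- out | c(v[-seq_len(o)], rep(FALSE, o)) |
        c(rep(FALSE, o), v[seq_len(n - o)])
    }
    out
  }
  joint <- (flag[, 1] & near(flag[, 2], coincidence)) |
    (flag[, 2] & near(flag[, 1], coincidence))
  r <- rle(joint)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= min_frames)
  ev <- data.frame(start_frame = rfi$frame[starts[keep]],
                   duration = r$lengths[keep])
  for (ch in chans) {
    ev[[paste0("peak_", ch)]] <- vapply(keep, function(i)
      max(rfi[[ch]][starts[i]:ends[i]]), numeric(1))
  }
  class(ev) <- c("flare_events", "data.frame")
  ev
}

#' Vesicle speed at versus away from flares
#'
#' Partitions the per-step speeds of a track into steps occurring at a flare
#' (either endpoint frame inside a flare's span) and steps away from flares.
#'
#' @param track a vesicle \code{track}.
#' @param flares \code{flare_events} for this track (frame indices must be
#'   on the same clock as the track's).
#' @param spacing micrometers per pixel per axis.
#' @param frame_interval seconds per frame.
#' @return list with \code{at} and \code{away} (speed vectors, um/s) and
#'   \code{mean_at}, \code{mean_away} (NA when a class is empty).
#' @export
speed_partition <- function(track, flares, spacing, frame_interval) {
  kin <- track_kinematics(track, spacing, frame_interval)
  in_flare <- function(f) {
    if (nrow(flares) == 0) return(rep(FALSE, length(f)))
    vapply(f, function(x)
      any(x >= flares$start_frame &
            x <= flares$start_frame + flares$duration - 1L), logical(1))
  }
  at <- in_flare(kin$from_frame) | in_flare(kin$to_frame)
  list(at = kin$speed_um_s[at], away = kin$speed_um_s[!at],
       mean_at = if (any(at)) mean(kin$speed_um_s[at]) else NA_real_,
       mean_away = if (any(!at)) mean(kin$speed_um_s[!at]) else NA_real_)
}
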