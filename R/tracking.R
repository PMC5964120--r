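#' Link per-frame objects into tracks
#'
#' Greedy nearest-neighbour frame-to-frame linking with gap closing. At each
#' frame, candidate (track, object) pairs are formed between open tracks and
#' the frame's objects; pairs are accepted in order of ascending centroid
#' distance (ties by smaller object label), subject to a search radius of
#' \code{max_disp * (gap + 1)} pixels where \code{gap} is the number of
#' missed frames since the track was last observed. A track is closed once
#' its gap exceeds \code{max_gap}; objects left unmatched start new tracks,
#' so every object belongs to exactly one track.
#'
#' @param objects_by_frame a \code{detection_series} or list of
#'   \code{labeled_objects}, one per frame in temporal order.
#' @param max_disp maximum frame-to-frame displacement in pixels (> 0).
#' @param max_gap maximum number of consecutive missed frames (>= 0).
#' @return list of class \code{track_set}; each element is a \code{track}:
#'   list with \code{id}, \code{channel}, \code{frame} (observed frame
#'   indices), \code{label} (object labels), \code{centroid} (n x d matrix,
#'   pixels), \code{intensity} (integrated), \code{size}.
#' @export
link_tracks <- function(objects_by_frame, max_disp = 5, max_gap = 2) {
  if (inherits(objects_by_frame, "detection_series")) {
    channel <- objects_by_frame$channel
    objects_by_frame <- objects_by_frame$frames
  } else {
    channel <- if (length(objects_by_frame))
      objects_by_frame[[1]]$channel else NA_integer_
  }
  if (max_disp <= 0) stop("max_disp must be positive")
  if (max_gap < 0) stop("max_gap must be >= 0")
  nt <- length(objects_by_frame)
  tracks <- list()
  open <- list() # each: track index, last frame, last centroid
  for (t in seq_len(nt)) {
    lo <- objects_by_frame[[t]]
    tab <- lo$objects
    axes <- grep("_px$", names(tab), value = TRUE)
    cen <- as.matrix(tab[, axes, drop = FALSE])
    nobj <- nrow(tab)
    assigned_obj <- rep(FALSE, nobj)
    if (length(open) && nobj) {
      cand <- do.call(rbind, lapply(seq_along(open), function(k) {
        o <- open[[k]]
        gap <- t - o$last_frame - 1L
        radius <- max_disp * (gap + 1)
        dists <- sqrt(colSums((t(cen) - o$last_centroid)^2))
        ok <- which(dists <= radius)
        if (!length(ok)) return(NULL)
        cbind(track = k, obj = ok, dist = dists[ok])
      }))
      if (!is.null(cand) && nrow(cand)) {
        cand <- cand[order(cand[, "dist"], cand[, "obj"]), , drop = FALSE]
        used_track <- rep(FALSE, length(open))
        for (i in seq_len(nrow(cand))) {
          k <- cand[i, "track"]; j <- cand[i, "obj"]
          if (used_track[k] || assigned_obj[j]) next
          used_track[k] <- TRUE
          assigned_obj[j] <- TRUE
          ti <- open[[k]]$track
          tr <- tracks[[ti]]
          tr$frame <- c(tr$frame, t)
          tr$label <- c(tr$label, tab$label[j])
          tr$centroid <- rbind(tr$centroid, cen[j, ])
          tr$intensity <- c(tr$intensity, tab$integrated[j])
          tr$size <- c(tr$size, tab$size[j])
          tracks[[ti]] <- tr
          open[[k]]$last_frame <- t
          open[[k]]$last_centroid <- cen[j, ]
        }
      }
    }
    for (j in which(!assigned_obj)) {
      tr <- list(id = length(tracks) + 1L, channel = channel,
                 frame = t, label = tab$label[j],
                 centroid = matrix(cen[j, ], nrow = 1),
                 intensity = tab$integrated[j], size = tab$size[j])
      class(tr) <- "track"
      tracks[[length(tracks) + 1L]] <- tr
      open[[length(open) + 1L]] <- list(track = length(tracks),
                                        last_frame = t,
                                        last_centroid = cen[j, ])
    }
    open <- Filter(function(o) t - o$last_frame <= max_gap, open)
  }
  structure(tracks, class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  cat("<track_set>", length(x), "tracks; lifetimes:",
      paste(utils::head(vapply(x, function(t) length(t$frame), 1L), 10),
            collapse = ","),
      if (length(x) > 10) "..." else "", "\n")
  invisible(x)
}

#' Lifetime of a track
#' @param track a \code{track}.
#' @return number of observed frames (gap frames excluded).
#' @export
track_lifetime <- function(track) length(track$frame)

#' Per-step speeds of a track
#'
#' Physical displacement between consecutive observations divided by the
#' elapsed time, which across a gap is the true elapsed time (so a step
#' spanning a 2-frame gap is averaged over that whole interval).
#'
#' @param track a \code{track}.
#' @param spacing micrometers per pixel per axis (matching centroid columns).
#' @param frame_interval seconds between frames.
#' @return data.frame with \code{from_frame}, \code{to_frame},
#'   \code{displacement_um}, \code{dt_s} and \code{speed_um_s}; one row per
#'   consecutive observed pair (observations - 1 rows).
#' @export
track_kinematics <- function(track, spacing, frame_interval) {
  n <- track_lifetime(track)
  if (n < 2) stop("track must have at least 2 observations")
  if (length(spacing) != ncol(track$centroid))
    stop("spacing must match track dimensionality")
  phys <- sweep(track$centroid, 2, spacing, "*")
  disp <- sqrt(rowSums((phys[-1, , drop = FALSE] -
                        phys[-n, , drop = FALSE])^2))
  dt <- diff(track$frame) * frame_interval
  data.frame(from_frame = track$frame[-n], to_frame = track$frame[-1],
             displacement_um = disp, dt_s = dt, speed_um_s = disp / dt)
}
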