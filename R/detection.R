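#' Band-pass particle enhancement
#'
#' Difference-of-Gaussians filter that suppresses background and flat
#' gradients while enhancing diffraction-limited feature points, the standard
#' pre-filter before intensity thresholding of spots. The band is set by
#' \code{spot_sigma} (small scale) and \code{3 * spot_sigma} (large scale);
#' negative response values are clipped to zero.
#'
#' @param frame 2-d or 3-d numeric array of intensities.
#' @param spot_sigma expected spot scale in pixels; must be positive.
#' @return array of the same shape holding the clipped band-pass response.
#' @examples
#' f <- matrix(100, 32, 32)  # constant frame -> all-zero response
#' max(enhance_particles(f, 1.5))
#' @export
enhance_particles <- function(frame, spot_sigma) {
  if (!is.numeric(spot_sigma) || spot_sigma <= 0)
    stop("spot_sigma must be positive")
  check_finite(frame, "frame")
  if (is.null(dim(frame))) stop("frame must be a 2-d or 3-d array")
  resp <- gaussian_blur(frame, spot_sigma) -
    gaussian_blur(frame, 3 * spot_sigma)
  resp[resp < 0] <- 0
  resp
}

#' Choose a segmentation threshold
#'
#' Returns the intensity threshold used for segmentation: either Otsu's
#' method (computed on the supplied frame, typically the enhanced response)
#' or a manual value passed through unchanged. The value actually used is
#' meant to be logged by the caller for reproducibility.
#'
#' @param frame numeric array the threshold refers to.
#' @param method \code{"otsu"} or \code{"manual"}.
#' @param manual_value required when \code{method = "manual"}.
#' @return the threshold as a single numeric value.
#' @export
threshold_value <- function(frame, method = c("otsu", "manual"),
                            manual_value = NULL) {
  method <- match.arg(method)
  if (method == "manual") {
    if (is.null(manual_value)) stop("manual thresholding requires manual_value")
    return(as.numeric(manual_value))
  }
  check_finite(frame, "frame")
  rng <- range(frame)
  if (diff(rng) == 0)
    stop("Otsu threshold undefined on a constant frame (no separable classes)")
  otsu_pooled(as.numeric(frame))
}

# Otsu on a pooled pixel sample (values need not form an image).
otsu_pooled <- function(values) {
  rng <- range(values)
  if (diff(rng) == 0) stop("Otsu threshold undefined on constant values")
  scaled <- (values - rng[1]) / diff(rng)
  # EBImage::otsu expects image-shaped grayscale data in a known range
  img <- EBImage::as.Image(matrix(scaled, ncol = 1))
  th <- EBImage::otsu(img, range = c(0, 1), levels = 256)
  th * diff(rng) + rng[1]
}

#' Segment a frame into labeled objects
#'
#' Connected components of pixels strictly above \code{threshold}, using
#' 8-connectivity in 2-d and 26-connectivity in 3-d. Components smaller than
#' \code{min_size} pixels are discarded; surviving labels are renumbered
#' 1..n in order of decreasing size (ties broken by scan order). Centroids
#' are intensity-weighted using \code{intensity} (by default the thresholded
#' frame itself, but the raw frame can be supplied when segmentation runs on
#' an enhanced response).
#'
#' @param frame numeric array the threshold is applied to.
#' @param threshold finite intensity cutoff.
#' @param min_size minimum object size in pixels; default 4 (2-d) / 8 (3-d).
#' @param spacing physical sample spacing per axis (micrometers), used only
#'   for physical measurements downstream; stored with the result.
#' @param intensity optional array for intensity statistics and centroid
#'   weighting; same shape as \code{frame}.
#' @param frame_index,channel bookkeeping indices stored with the result.
#' @return A \code{labeled_objects} object: list with \code{labels} (integer
#'   array) and \code{objects} (one row per object: label, centroid, size,
#'   integrated/mean intensity, bounding box).
#' @export
segment_frame <- function(frame, threshold, min_size = NULL, spacing = NULL,
                          intensity = NULL, frame_index = NA_integer_,
                          channel = NA_integer_) {
  if (!is.finite(threshold)) stop("threshold must be finite")
  check_finite(frame, "frame")
  d <- dim(frame)
  nd <- length(d)
  if (is.null(min_size)) min_size <- if (nd == 2) 4L else 8L
  if (min_size < 1) stop("min_size must be >= 1")
  if (is.null(intensity)) intensity <- frame
  if (!identical(dim(intensity), d)) stop("intensity shape mismatch")
  raw <- label_components(frame > threshold)
  labeled_objects(raw, intensity, min_size = min_size, spacing = spacing,
                  frame_index = frame_index, channel = channel)
}

# Build a labeled_objects result from a raw integer label array: apply the
# size filter, renumber by descending size and tabulate per-object summaries.
labeled_objects <- function(raw_labels, intensity, min_size = 1L,
                            spacing = NULL, frame_index = NA_integer_,
                            channel = NA_integer_) {
  d <- dim(raw_labels)
  nd <- length(d)
  axes <- if (nd == 2) c("y", "x") else c("z", "y", "x")
  fg <- which(raw_labels > 0L)
  out_labels <- array(0L, dim = d)
  empty <- stats::setNames(
    as.data.frame(matrix(numeric(0), 0, 4 + 3 * nd)),
    c("label", paste0(axes, "_px"), "size", "integrated", "mean",
      paste0(axes, "_min"), paste0(axes, "_max")))
  res <- list(labels = out_labels, objects = empty, frame = frame_index,
              channel = channel, spacing = spacing)
  class(res) <- "labeled_objects"
  if (length(fg) == 0L) return(res)
  ids <- raw_labels[fg]
  sizes <- tabulate(ids)
  keep_old <- which(sizes >= min_size)
  if (length(keep_old) == 0L) return(res)
  ord <- keep_old[order(-sizes[keep_old], keep_old)]
  remap <- integer(length(sizes))
  remap[ord] <- seq_along(ord)
  sel <- remap[ids] > 0L
  fg <- fg[sel]
  new_ids <- remap[ids[sel]]
  out_labels[fg] <- new_ids
  coords <- arrayInd(fg, d)
  w <- intensity[fg]
  wsum <- as.numeric(tapply(w, new_ids, sum))
  cen <- sapply(seq_len(nd), function(a)
    as.numeric(tapply(w * coords[, a], new_ids, sum)) / wsum)
  cen <- matrix(cen, ncol = nd)
  tab <- data.frame(label = seq_along(ord))
  for (a in seq_len(nd)) tab[[paste0(axes[a], "_px")]] <- cen[, a]
  tab$size <- as.integer(tabulate(new_ids))
  tab$integrated <- wsum
  tab$mean <- wsum / tab$size
  for (a in seq_len(nd)) {
    tab[[paste0(axes[a], "_min")]] <-
      as.integer(tapply(coords[, a], new_ids, min))
    tab[[paste0(axes[a], "_max")]] <-
      as.integer(tapply(coords[, a], new_ids, max))
  }
  res$labels <- out_labels
  res$objects <- tab
  res
}

#' @export
print.labeled_objects <- function(x, ...) {
  cat("<labeled_objects> frame", x$frame, "channel", x$channel, "-",
      nrow(x$objects), "objects\n")
  invisible(x)
}

#' Split touching objects at intensity maxima
#'
#' Within each labeled component, local intensity maxima separated by at
#' least \code{min_separation} pixels become markers, and the component is
#' re-partitioned by a marker-based watershed on the inverted intensity
#' (implemented as ordered flooding from the markers downhill). Components
#' with a single surviving maximum are left unchanged. The union of
#' foreground pixels is never altered.
#'
#' @param labels a \code{labeled_objects} result.
#' @param intensity intensity array used to locate maxima and order flooding.
#' @param min_separation minimum marker separation in pixels (>= 1).
#' @return a new \code{labeled_objects} with split components.
#' @export
split_touching_objects <- function(labels, intensity, min_separation = 3) {
  if (min_separation < 1) stop("min_separation must be >= 1")
  lab <- labels$labels
  d <- dim(lab)
  if (!identical(dim(intensity), d)) stop("intensity shape mismatch")
  nlab <- max(lab)
  out <- array(0L, dim = d)
  next_id <- 0L
  for (l in seq_len(nlab)) {
    px <- which(lab == l)
    comp_mask <- array(FALSE, dim = d)
    comp_mask[px] <- TRUE
    peaks <- local_maxima(intensity, comp_mask, min_separation)
    if (nrow(peaks) <= 1L) {
      next_id <- next_id + 1L
      out[px] <- next_id
      next
    }
    sub <- flood_from_markers(comp_mask, intensity, peaks)
    out[px] <- sub[px] + next_id
    next_id <- next_id + max(sub)
  }
  labeled_objects(out, intensity, min_size = 1L, spacing = labels$spacing,
                  frame_index = labels$frame, channel = labels$channel)
}

# Marker-based watershed by ordered flooding: pixels are claimed in order of
# decreasing intensity; a pixel joins the label of an already-claimed
# neighbour (the brightest one on ties), so basins grow downhill from the
# markers. Unreached pixels (separated plateaus) fall to the nearest marker.
flood_from_markers <- function(mask, intensity, markers) {
  d <- dim(mask)
  nd <- length(d)
  sub <- array(0L, dim = d)
  for (i in seq_len(nrow(markers))) {
    idx <- markers[i, 1]
    if (nd >= 2) idx <- idx + (markers[i, 2] - 1) * d[1]
    if (nd == 3) idx <- idx + (markers[i, 3] - 1) * d[1] * d[2]
    sub[idx] <- i
  }
  px <- which(mask)
  ord <- px[order(-intensity[px])]
  coords <- arrayInd(ord, d)
  offsets <- as.matrix(do.call(expand.grid, rep(list(-1:1), nd)))
  offsets <- offsets[rowSums(abs(offsets)) > 0, , drop = FALSE]
  for (pass in 1:2) {
    for (i in seq_along(ord)) {
      if (sub[ord[i]] > 0L) next
      best <- 0L; best_int <- -Inf
      for (k in seq_len(nrow(offsets))) {
        nb <- coords[i, ] + offsets[k, ]
        if (any(nb < 1L) || any(nb > d)) next
        lin <- nb[1]
        if (nd >= 2) lin <- lin + (nb[2] - 1) * d[1]
        if (nd == 3) lin <- lin + (nb[3] - 1) * d[1] * d[2]
        if (sub[lin] > 0L && intensity[lin] > best_int) {
          best <- sub[lin]; best_int <- intensity[lin]
        }
      }
      if (best > 0L) sub[ord[i]] <- best
    }
    if (!any(sub[px] == 0L)) break
  }
  if (any(sub[px] == 0L)) { # isolated leftovers: nearest marker
    left <- px[sub[px] == 0L]
    lc <- arrayInd(left, d)
    for (i in seq_along(left)) {
      dist2 <- rowSums(sweep(markers, 2, lc[i, ])^2)
      sub[left[i]] <- which.min(dist2)
    }
  }
  sub
}

#' Detect objects in every frame of one channel
#'
#' Runs particle enhancement and segmentation over a whole time series. The
#' threshold is chosen once per channel from the pooled enhanced pixels of
#' all frames (Otsu by default), mirroring the per-dataset threshold choice
#' of interactive analysis while keeping empty early frames empty: a frame
#' with no true signal contributes nothing above a threshold anchored by the
#' real spots. The chosen value is recorded in the result.
#'
#' @param series an \code{image_series}.
#' @param channel channel index or name.
#' @param spot_sigma expected spot scale in pixels for enhancement.
#' @param threshold optional manual threshold on the enhanced response;
#'   \code{NULL} selects Otsu on the pooled enhanced stack.
#' @param min_size minimum object size in pixels.
#' @param split split touching objects at intensity maxima.
#' @param min_separation marker separation for splitting, pixels.
#' @return list of class \code{detection_series}: per-frame
#'   \code{labeled_objects} in \code{$frames}, plus the \code{$threshold}
#'   used and the call parameters.
#' @export
detect_channel <- function(series, channel, spot_sigma = 1.2,
                           threshold = NULL, min_size = NULL, split = FALSE,
                           min_separation = 3) {
  if (is.character(channel)) channel <- match(channel, series$channels)
  nt <- n_frames(series)
  sp <- series_spacing(series)
  enhanced <- vector("list", nt)
  raws <- vector("list", nt)
  for (t in seq_len(nt)) {
    raws[[t]] <- get_frame(series, t, channel)
    enhanced[[t]] <- enhance_particles(raws[[t]], spot_sigma)
  }
  if (is.null(threshold)) {
    pooled <- unlist(enhanced, use.names = FALSE)
    pos <- pooled[pooled > 0] # clipped zeros carry no class information
    if (length(pos) < 2 || diff(range(pos)) == 0)
      stop("cannot choose an automatic threshold: no enhanced signal")
    threshold <- otsu_pooled(pos)
  }
  frames <- vector("list", nt)
  for (t in seq_len(nt)) {
    lo <- segment_frame(enhanced[[t]], threshold, min_size = min_size,
                        spacing = sp, intensity = raws[[t]],
                        frame_index = t, channel = channel)
    if (split && nrow(lo$objects) > 0)
      lo <- split_touching_objects(lo, raws[[t]], min_separation)
    frames[[t]] <- lo
  }
  structure(list(frames = frames, channel = channel, threshold = threshold,
                 spot_sigma = spot_sigma, spacing = sp,
                 frame_interval = series$frame_interval),
            class = "detection_series")
}

#' @export
print.detection_series <- function(x, ...) {
  cat("<detection_series> channel", x$channel, "-", length(x$frames),
      "frames, threshold", signif(x$threshold, 4), "\n")
  invisible(x)
}
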