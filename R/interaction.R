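#' Object-based touch test between a vesicle and microclusters
#'
#' A vesicle is in contact with a microcluster when its pixel mask, dilated
#' by \code{tolerance} pixels (Euclidean ball), overlaps any cluster pixel.
#' Among touched clusters the label with the greatest overlap is returned
#' (ties to the smaller label).
#'
#' @param vesicle_mask logical array, the vesicle's pixels.
#' @param cluster_labels integer label array of the clusters, same geometry.
#' @param tolerance dilation radius in pixels (>= 0).
#' @return list with \code{contact} (logical) and \code{cluster} (label id,
#'   0 when no contact).
#' @export
touch_test <- function(vesicle_mask, cluster_labels, tolerance = 1) {
  d <- dim(vesicle_mask)
  if (!identical(d, dim(cluster_labels)))
    stop("vesicle mask and cluster labels must share geometry")
  if (tolerance < 0) stop("tolerance must be >= 0")
  px <- which(vesicle_mask)
  if (length(px) == 0L) return(list(contact = FALSE, cluster = 0L))
  nd <- length(d)
  coords <- arrayInd(px, d)
  off <- ball_offsets(tolerance, nd)
  hits <- integer(0)
  for (i in seq_len(nrow(off))) {
    nb <- sweep(coords, 2, off[i, ], "+")
    ok <- rep(TRUE, nrow(nb))
    for (a in seq_len(nd)) ok <- ok & nb[, a] >= 1L & nb[, a] <= d[a]
    if (!any(ok)) next
    lin <- nb[ok, 1]
    if (nd >= 2) lin <- lin + (nb[ok, 2] - 1L) * d[1]
    if (nd == 3) lin <- lin + (nb[ok, 3] - 1L) * d[1] * d[2]
    hits <- c(hits, lin)
  }
  hits <- unique(hits)
  labs <- cluster_labels[hits]
  labs <- labs[labs > 0L]
  if (length(labs) == 0L) return(list(contact = FALSE, cluster = 0L))
  counts <- table(labs)
  best <- as.integer(names(counts))[counts == max(counts)]
  list(contact = TRUE, cluster = min(best))
}

#' Lifetime colocalization of a vesicle track with microclusters
#'
#' Applies the touch test at every observed frame of the track and summarises
#' the per-track lifetime-colocalization fraction: the fraction of observed
#' frames in which the vesicle touches a microcluster. Gap frames are not in
#' the denominator - a vesicle that is not detected cannot be scored.
#'
#' @param track a vesicle \code{track}.
#' @param clusters_by_frame \code{detection_series} (or list of
#'   \code{labeled_objects}) for the cluster channel; must cover every
#'   observed frame of the track.
#' @param vesicles_by_frame \code{detection_series} for the vesicle channel,
#'   supplying the track's segmentation masks.
#' @param tolerance touch tolerance in pixels.
#' @return an \code{interaction_record}: list with \code{track_id},
#'   \code{frame}, \code{contact}, \code{cluster}, and
#'   \code{lifetime_fraction}.
#' @export
lifetime_colocalization <- function(track, clusters_by_frame,
                                    vesicles_by_frame, tolerance = 1) {
  cl <- if (inherits(clusters_by_frame, "detection_series"))
    clusters_by_frame$frames else clusters_by_frame
  ve <- if (inherits(vesicles_by_frame, "detection_series"))
    vesicles_by_frame$frames else vesicles_by_frame
  n <- track_lifetime(track)
  contact <- logical(n)
  cluster <- integer(n)
  for (i in seq_len(n)) {
    f <- track$frame[i]
    if (f > length(cl) || is.null(cl[[f]]))
      stop("no cluster segmentation for frame ", f)
    if (f > length(ve) || is.null(ve[[f]]))
      stop("no vesicle segmentation for frame ", f)
    mask <- ve[[f]]$labels == track$label[i]
    tt <- touch_test(mask, cl[[f]]$labels, tolerance)
    contact[i] <- tt$contact
    cluster[i] <- tt$cluster
  }
  structure(list(track_id = track$id, frame = track$frame,
                 contact = contact, cluster = cluster,
                 lifetime = n,
                 lifetime_fraction = mean(contact)),
            class = "interaction_record")
}

#' @export
print.interaction_record <- function(x, ...) {
  cat(sprintf("<interaction_record> track %d: %d/%d frames in contact (%.1f%%)\n",
              x$track_id, sum(x$contact), x$lifetime,
              100 * x$lifetime_fraction))
  invisible(x)
}

#' Population-level vesicle-microcluster association
#'
#' Percentage of vesicle tracks (with at least \code{min_lifetime} observed
#' frames) whose lifetime-colocalization fraction reaches
#' \code{lifetime_threshold}; the population statistic behind "fraction of
#' vesicles associated with microclusters for most of their lifetime".
#'
#' @param records list of \code{interaction_record}s.
#' @param lifetime_threshold fraction in (0, 1]; default 0.75.
#' @param min_lifetime minimum observed frames for a track to qualify.
#' @return percentage (0-100) of qualifying tracks above the threshold.
#' @export
population_association <- function(records, lifetime_threshold = 0.75,
                                   min_lifetime = 5) {
  if (!(lifetime_threshold > 0 && lifetime_threshold <= 1))
    stop("lifetime_threshold must be in (0, 1]")
  life <- vapply(records, function(r) r$lifetime, 1)
  frac <- vapply(records, function(r) r$lifetime_fraction, 1)
  qual <- life >= min_lifetime
  if (!any(qual)) stop("no tracks reach min_lifetime; percentage undefined")
  100 * mean(frac[qual] >= lifetime_threshold)
}

#' Pearson correlation between two channels
#'
#' Sample Pearson correlation of pixel intensities over an optional mask.
#'
#' @param channel_a,channel_b numeric arrays of identical shape.
#' @param mask optional logical array selecting pixels; default all.
#' @return correlation coefficient in [-1, 1].
#' @export
pearson_coefficient <- function(channel_a, channel_b, mask = NULL) {
  if (!identical(dim(channel_a), dim(channel_b)))
    stop("channels must share geometry")
  if (is.null(mask)) mask <- array(TRUE, dim = dim(channel_a))
  a <- channel_a[mask]; b <- channel_b[mask]
  if (length(a) < 2) stop("need at least 2 masked pixels")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero variance within mask; correlation undefined")
  stats::cor(a, b)
}

#' Costes block-randomization significance test
#'
#' Builds a null distribution for the Pearson coefficient by scrambling one
#' channel in blocks: channel A is cut into \code{block x block} tiles lying
#' wholly inside the mask, tile contents are permuted uniformly at random,
#' and the correlation with the unshuffled channel B is recomputed per
#' iteration (over the tiled region, for comparability with the observed
#' value). The p value uses the add-one estimator
#' \code{(count(null >= observed) + 1) / (iterations + 1)}.
#'
#' @param channel_a,channel_b 2-d numeric matrices.
#' @param mask optional logical matrix; default all pixels.
#' @param block tile edge in pixels (>= 1); choose about twice the PSF sigma
#'   so tiles are roughly independent structural units.
#' @param iterations number of scrambles (>= 1).
#' @param seed integer seed for the scrambles.
#' @return list of class \code{costes_result}: \code{observed_r},
#'   \code{null_r}, \code{p_value}, \code{block}, \code{iterations},
#'   \code{seed}.
#' @export
costes_randomization <- function(channel_a, channel_b, mask = NULL,
                                 block = 5, iterations = 99, seed = 1) {
  if (block < 1) stop("block must be >= 1")
  if (iterations < 1) stop("iterations must be >= 1")
  d <- dim(channel_a)
  if (length(d) != 2) stop("Costes randomization expects 2-d frames")
  if (!identical(d, dim(channel_b))) stop("channels must share geometry")
  if (is.null(mask)) mask <- array(TRUE, dim = d)
  by <- floor(d[1] / block); bx <- floor(d[2] / block)
  tiles <- list()
  for (ty in seq_len(by)) for (tx in seq_len(bx)) {
    ys <- (ty - 1) * block + seq_len(block)
    xs <- (tx - 1) * block + seq_len(block)
    if (all(mask[ys, xs])) tiles[[length(tiles) + 1L]] <- list(ys = ys, xs = xs)
  }
  if (length(tiles) < 2) stop("fewer than 2 whole tiles inside the mask")
  idx <- lapply(tiles, function(t)
    as.vector(outer(t$ys, (t$xs - 1) * d[1], "+")))
  region <- unlist(idx)
  a <- channel_a[region]; b <- channel_b[region]
  observed <- pearson_coefficient(matrix(a), matrix(b))
  npx <- block * block
  null_r <- with_seed(seed, {
    vapply(seq_len(iterations), function(i) {
      perm <- sample.int(length(tiles))
      a_shuf <- as.numeric(channel_a)[unlist(idx[perm])]
      stats::cor(a_shuf, b)
    }, numeric(1))
  })
  p <- (sum(null_r >= observed) + 1) / (iterations + 1)
  structure(list(observed_r = observed, null_r = null_r, p_value = p,
                 block = block, iterations = iterations, seed = seed),
            class = "costes_result")
}

#' @export
print.costes_result <- function(x, ...) {
  cat(sprintf("<costes_result> r = %.3f, null mean = %.3f, p = %.4g (%d iterations, block %d)\n",
              x$observed_r, mean(x$null_r), x$p_value, x$iterations, x$block))
  invisible(x)
}

#' Spatiotemporal map of vesicle tracks over microclusters
#'
#' Renders the union of cluster footprints with every vesicle track path
#' drawn segment by segment, coloured by the contact state of the segment's
#' starting frame; also returns the underlying tidy table (one row per track
#' observation with its position, time and contact state).
#'
#' @param records list of \code{interaction_record}s.
#' @param tracks matching \code{track_set}.
#' @param clusters_by_frame cluster-channel \code{detection_series}.
#' @param file optional PNG path; when given the map image is written there.
#' @return (invisibly) list with \code{table} (data.frame) and the
#'   \code{file} written (or NULL).
#' @export
spatiotemporal_map <- function(records, tracks, clusters_by_frame,
                               file = NULL) {
  cl <- if (inherits(clusters_by_frame, "detection_series"))
    clusters_by_frame$frames else clusters_by_frame
  rec_by_id <- stats::setNames(records,
                               vapply(records, function(r) r$track_id, 1))
  rows <- list()
  for (tr in tracks) {
    r <- rec_by_id[[as.character(tr$id)]]
    if (is.null(r)) next
    cen <- tr$centroid
    d <- ncol(cen)
    rows[[length(rows) + 1L]] <- data.frame(
      track_id = tr$id, frame = tr$frame,
      y_px = cen[, d - 1], x_px = cen[, d],
      contact = r$contact)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(track_id = integer(0), frame = integer(0),
               y_px = numeric(0), x_px = numeric(0), contact = logical(0))
  if (!is.null(file)) {
    footprint <- NULL
    for (lo in cl) {
      m <- lo$labels > 0
      if (length(dim(m)) == 3) m <- apply(m, c(2, 3), any)
      footprint <- if (is.null(footprint)) m else footprint | m
    }
    d <- dim(footprint)
    grDevices::png(file, width = 640, height = 640)
    graphics::par(mar = c(2, 2, 1, 1))
    graphics::image(x = seq_len(d[2]), y = seq_len(d[1]),
                    z = t(footprint)[, rev(seq_len(d[1])), drop = FALSE],
                    col = c("white", "grey70"), useRaster = TRUE,
                    xlab = "", ylab = "", axes = FALSE)
    graphics::box()
    for (id in unique(tab$track_id)) {
      s <- tab[tab$track_id == id, ]
      n <- nrow(s)
      if (n < 2) next
      segcol <- ifelse(s$contact[-n], "goldenrod2", "purple3")
      graphics::segments(s$x_px[-n], d[1] - s$y_px[-n] + 1,
                         s$x_px[-1], d[1] - s$y_px[-1] + 1,
                         col = segcol, lwd = 2)
    }
    grDevices::dev.off()
  }
  invisible(list(table = tab, file = file))
}
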