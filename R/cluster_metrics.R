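#' Per-cluster area/volume and intensity statistics
#'
#' Physical area (2-d, um^2) or volume (3-d, um^3) plus integrated and mean
#' intensity for every labeled cluster, with a per-image summary. Totals are
#' invariant to label renumbering.
#'
#' @param labels a \code{labeled_objects} result.
#' @param intensity raw intensity array, same geometry as the label image.
#' @param spacing micrometers per sample per axis.
#' @return list of class \code{cluster_stats}: \code{per_cluster}
#'   (data.frame: label, size_px, area_um2 or volume_um3, integrated, mean)
#'   and \code{summary} (count, mean area/volume, mean intensity).
#' @export
cluster_stats <- function(labels, intensity, spacing) {
  lab <- labels$labels
  if (!identical(dim(lab), dim(intensity)))
    stop("labels and intensity must share geometry")
  nd <- length(dim(lab))
  if (length(spacing) != nd) stop("spacing must have one entry per axis")
  unit <- prod(spacing)
  measure <- if (nd == 2) "area_um2" else "volume_um3"
  fg <- which(lab > 0L)
  if (length(fg) == 0L) {
    per <- data.frame(label = integer(0), size_px = integer(0))
    per[[measure]] <- numeric(0)
    per$integrated <- numeric(0); per$mean <- numeric(0)
    return(structure(list(per_cluster = per,
                          summary = data.frame(count = 0L)),
                     class = "cluster_stats"))
  }
  ids <- lab[fg]
  size <- tabulate(ids)
  present <- which(size > 0)
  integ <- as.numeric(tapply(intensity[fg], ids, sum))
  per <- data.frame(label = present, size_px = size[present])
  per[[measure]] <- size[present] * unit
  per$integrated <- integ
  per$mean <- integ / size[present]
  summary <- data.frame(count = nrow(per),
                        mean_size = mean(per[[measure]]),
                        mean_integrated = mean(per$integrated),
                        mean_intensity = mean(per$mean))
  names(summary)[2] <- paste0("mean_", measure)
  structure(list(per_cluster = per, summary = summary),
            class = "cluster_stats")
}

#' @export
print.cluster_stats <- function(x, ...) {
  cat("<cluster_stats>", nrow(x$per_cluster), "clusters\n")
  print(x$summary)
  invisible(x)
}

#' Normalized multi-channel line-scan profile
#'
#' Samples intensity along the segment from \code{p0} to \code{p1} at
#' pixel-pitch steps with bilinear interpolation, averaging across
#' \code{width} pixels perpendicular to the scan. Each channel is background
#' subtracted (negatives clipped to zero) and divided by its maximum, so a
#' channel with signal peaks at 1; a channel whose maximum does not exceed
#' background is returned as all zero with a warning recorded.
#'
#' @param images 3-d array \code{C x Y x X} (or a single \code{Y x X}
#'   matrix, treated as one channel).
#' @param p0,p1 scan endpoints as \code{c(y, x)} pixel coordinates.
#' @param width perpendicular averaging width in pixels (>= 1).
#' @param pixel_pitch micrometers per pixel (sets positions and step).
#' @param background either a single number or vector per channel, or
#'   \code{NULL} for the default: the 1st percentile of each channel's raw
#'   profile along the scan.
#' @param normalize \code{"max"} (peak = 1) or \code{"mean"}.
#' @return data.frame of class \code{line_scan_profile}: \code{position_um}
#'   plus one column per channel; attribute \code{"warnings"} lists channels
#'   without signal above background.
#' @export
line_scan_profile <- function(images, p0, p1, width = 1, pixel_pitch = 1,
                              background = NULL,
                              normalize = c("max", "mean")) {
  normalize <- match.arg(normalize)
  if (length(dim(images)) == 2) {
    images <- array(images, dim = c(1, dim(images)))
  }
  dC <- dim(images)[1]; dY <- dim(images)[2]; dX <- dim(images)[3]
  if (width < 1) stop("width must be >= 1")
  for (p in list(p0, p1)) {
    if (p[1] < 1 || p[1] > dY || p[2] < 1 || p[2] > dX)
      stop("scan endpoints must lie inside the image")
  }
  v <- c(p1[1] - p0[1], p1[2] - p0[2])
  len <- sqrt(sum(v^2))
  if (len == 0) stop("degenerate scan: endpoints coincide")
  u <- v / len
  perp <- c(-u[2], u[1])
  nstep <- floor(len) + 1L
  tpos <- seq(0, len, length.out = nstep)
  offs <- seq_len(width) - (width + 1) / 2
  bilinear <- function(ch, y, x) {
    y <- pmin(pmax(y, 1), dY); x <- pmin(pmax(x, 1), dX)
    y0 <- pmin(floor(y), dY - 1); x0 <- pmin(floor(x), dX - 1)
    fy <- y - y0; fx <- x - x0
    m <- matrix(images[ch, , ], dY, dX)
    m[cbind(y0, x0)] * (1 - fy) * (1 - fx) +
      m[cbind(y0 + 1, x0)] * fy * (1 - fx) +
      m[cbind(y0, x0 + 1)] * (1 - fy) * fx +
      m[cbind(y0 + 1, x0 + 1)] * fy * fx
  }
  prof <- matrix(0, nstep, dC)
  for (ch in seq_len(dC)) {
    acc <- numeric(nstep)
    for (o in offs) {
      y <- p0[1] + tpos * u[1] + o * perp[1]
      x <- p0[2] + tpos * u[2] + o * perp[2]
      acc <- acc + bilinear(ch, y, x)
    }
    prof[, ch] <- acc / width
  }
  if (is.null(background)) {
    background <- apply(prof, 2, stats::quantile, probs = 0.01, names = FALSE)
  } else if (length(background) == 1) {
    background <- rep(background, dC)
  }
  warnings <- character(0)
  for (ch in seq_len(dC)) {
    p <- prof[, ch] - background[ch]
    p[p < 0] <- 0
    top <- if (normalize == "max") max(p) else mean(p)
    if (top <= 0) {
      warnings <- c(warnings,
                    sprintf("channel %d has no signal above background", ch))
      warning("channel ", ch, " has no signal above background; ",
              "profile returned as zero")
      prof[, ch] <- 0
    } else {
      prof[, ch] <- p / top
    }
  }
  out <- data.frame(position_um = tpos * pixel_pitch)
  for (ch in seq_len(dC)) out[[paste0("ch", ch)]] <- prof[, ch]
  class(out) <- c("line_scan_profile", "data.frame")
  attr(out, "warnings") <- warnings
  attr(out, "geometry") <- list(p0 = p0, p1 = p1, width = width,
                                pixel_pitch = pixel_pitch,
                                background = background)
  out
}

#' Two-group comparison of cluster measurements
#'
#' Thin convenience wrapper around Welch's two-tailed t test for comparing a
#' per-cluster measurement between conditions.
#'
#' @param x,y numeric vectors of per-cluster values for the two groups.
#' @return the \code{htest} from \code{\link[stats]{t.test}}.
#' @export
compare_groups <- function(x, y) stats::t.test(x, y)
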