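# Nominal detected-footprint model: the radius (px) of the pixel footprint
# that a Gaussian object of scale sigma presents after band-pass enhancement
# and automatic thresholding at the package defaults. Calibrated once on
# noise-free single-object frames; used to plant touch/no-touch geometry and
# to derive the ground-truth contact rule.
footprint_radius <- function(sigma) max(0.5, 2.2 * sigma - 1.2)

#' Simulation parameters for the two-phase synapse generator
#'
#' Builds a validated parameter set for \code{\link{simulate_timelapse}}.
#' The generative model has two phases: microclusters (cluster channel)
#' present at the contact plane from the first frame, and vesicles (vesicle
#' channel) recruited to the synapse after a lag drawn from
#' \code{vesicle_recruitment_window}. Associated vesicles travel on
#' piecewise-linear paths between cluster positions with dwells at clusters;
#' non-associated vesicles do a reflected random walk. Objects are rendered
#' as isotropic Gaussian spots (vesicles are sub-resolution, so their
#' physical size enters only through intensity); optional coincident
#' two-channel flares fire during dwells; camera noise is Poisson on
#' signal + background followed by additive Gaussian read noise.
#'
#' @param mode \code{"tirf2d"} (2D+t) or \code{"llsm3d"} (3D+t). In
#'   \code{tirf2d} recruitment is appearance (intensity switched on); in
#'   \code{llsm3d} vesicles descend in z from 3 um above the plane.
#' @param field_shape pixels per axis: \code{c(Y, X)} or \code{c(Z, Y, X)}.
#' @param pixel_pitch_xy lateral pixel size, micrometers.
#' @param z_step axial step, micrometers (\code{llsm3d} only).
#' @param frame_interval seconds between frames.
#' @param n_frames number of frames (>= 1).
#' @param n_clusters,cluster_sigma cluster count and Gaussian scale (px).
#' @param cluster_decay_half_life optional intensity half-life in frames.
#' @param n_vesicles vesicle count.
#' @param vesicle_recruitment_window \code{c(lag_min, lag_max)} seconds.
#' @param vesicle_speed micrometers per second.
#' @param assoc_fraction fraction of vesicles routed cluster-to-cluster.
#' @param dwell_prob probability of dwelling on each cluster visit.
#' @param dwell_duration dwell length, frames.
#' @param flare_prob probability of a flare per dwell.
#' @param flare_amplitude multiplicative two-channel flare factor.
#' @param flare_duration flare length, frames.
#' @param psf_sigma vesicle spot scale (px).
#' @param background photons per pixel.
#' @param read_noise_sd Gaussian read noise SD, photons.
#' @param noise_free disable all noise (deterministic rendering).
#' @param cluster_amplitude,vesicle_amplitude peak spot photons.
#' @param seed default seed used when \code{simulate_timelapse} is called
#'   without one.
#' @param plant internal: explicit planted geometry used by the presets.
#' @return object of class \code{generator_params}.
#' @seealso \code{\link{make_preset}}
#' @export
generator_params <- function(mode = c("tirf2d", "llsm3d"),
                             field_shape = c(128, 128),
                             pixel_pitch_xy = 0.1, z_step = NULL,
                             frame_interval = 1.5, n_frames = 100,
                             n_clusters = 10, cluster_sigma = 2,
                             cluster_decay_half_life = NULL,
                             n_vesicles = 10,
                             vesicle_recruitment_window = c(45, 60),
                             vesicle_speed = 0.25, assoc_fraction = 0.8,
                             dwell_prob = 0.7, dwell_duration = 15,
                             flare_prob = 0, flare_amplitude = 2,
                             flare_duration = 4, psf_sigma = 1.2,
                             background = 100, read_noise_sd = 3,
                             noise_free = FALSE,
                             cluster_amplitude = 300,
                             vesicle_amplitude = 250,
                             seed = 1, plant = NULL) {
  mode <- match.arg(mode)
  if (mode == "tirf2d" && length(field_shape) != 2)
    stop("tirf2d needs field_shape = c(Y, X)")
  if (mode == "llsm3d") {
    if (length(field_shape) != 3) stop("llsm3d needs field_shape = c(Z, Y, X)")
    if (is.null(z_step) || z_step <= 0) stop("llsm3d needs a positive z_step")
  }
  if (pixel_pitch_xy <= 0) stop("pixel_pitch_xy must be positive")
  if (frame_interval <= 0) stop("frame_interval must be positive")
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (n_clusters < 0 || n_vesicles < 0) stop("counts must be >= 0")
  w <- vesicle_recruitment_window
  if (length(w) != 2 || w[1] > w[2] || any(w < 0))
    stop("vesicle_recruitment_window must be c(lag_min, lag_max), lag_min <= lag_max")
  for (p in c(assoc_fraction, dwell_prob, flare_prob)) {
    if (p < 0 || p > 1) stop("fractions/probabilities must lie in [0, 1]")
  }
  structure(list(mode = mode, field_shape = as.numeric(field_shape),
                 pixel_pitch_xy = pixel_pitch_xy, z_step = z_step,
                 frame_interval = frame_interval,
                 n_frames = as.integer(n_frames),
                 n_clusters = as.integer(n_clusters),
                 cluster_sigma = cluster_sigma,
                 cluster_decay_half_life = cluster_decay_half_life,
                 n_vesicles = as.integer(n_vesicles),
                 vesicle_recruitment_window = w,
                 vesicle_speed = vesicle_speed,
                 assoc_fraction = assoc_fraction,
                 dwell_prob = dwell_prob,
                 dwell_duration = as.integer(dwell_duration),
                 flare_prob = flare_prob,
                 flare_amplitude = flare_amplitude,
                 flare_duration = as.integer(flare_duration),
                 psf_sigma = psf_sigma, background = background,
                 read_noise_sd = read_noise_sd, noise_free = noise_free,
                 cluster_amplitude = cluster_amplitude,
                 vesicle_amplitude = vesicle_amplitude,
                 seed = seed, plant = plant),
            class = "generator_params")
}

#' @export
print.generator_params <- function(x, ...) {
  cat("<generator_params>", x$mode, "|",
      paste(x$field_shape, collapse = "x"), "px |", x$n_frames, "frames @",
      x$frame_interval, "s |", x$n_clusters, "clusters,", x$n_vesicles,
      "vesicles", if (x$noise_free) "| noise-free" else "", "\n")
  invisible(x)
}

#' Named simulation presets
#'
#' Fixed parameter sets encoding documented study conditions with planted
#' ground truth:
#' \describe{
#'   \item{track145}{1 static cluster, 1 vesicle, 20 frames, noise-free;
#'     the vesicle's detected footprint touches the cluster in exactly 15 of
#'     its 20 detected frames (lifetime-contact fraction 0.75).}
#'   \item{track213}{as track145 but 19 of 20 contact frames (0.95).}
#'   \item{lag50}{2 s frame interval; cluster present from the first frame;
#'     the vesicle first touches the cluster 25 frame intervals in, i.e. at
#'     50 s; noise-free.}
#'   \item{paper_synapse}{20 vesicles over 200 frames with moderate noise;
#'     exactly 16 vesicles are planted at a true lifetime-contact fraction
#'     of at least 0.80 and the remaining 4 at 0.30 or below.}
#'   \item{two_phase_tirf, two_phase_llsm}{clusters from the first frame;
#'     vesicle recruitment lags drawn uniformly on 45-60 s; 1.5 s frame
#'     interval over > 200 s.}
#' }
#'
#' @param name one of the preset names above.
#' @return a \code{generator_params} with planted geometry and an
#'   \code{$plant$expected} list of the planted summary values.
#' @export
make_preset <- function(name) {
  presets <- c("track145", "track213", "lag50", "paper_synapse",
               "two_phase_tirf", "two_phase_llsm")
  if (!is.character(name) || length(name) != 1 || !(name %in% presets))
    stop("unknown preset '", paste(name, collapse = ","),
         "'; valid presets: ", paste(presets, collapse = ", "))
  switch(name,
         track145 = preset_single_track(contact_frames = 15),
         track213 = preset_single_track(contact_frames = 19),
         lag50 = preset_lag50(),
         paper_synapse = preset_paper_synapse(),
         two_phase_tirf = preset_two_phase("tirf2d"),
         two_phase_llsm = preset_two_phase("llsm3d"))
}

# One static cluster, one vesicle, 20 noise-free frames. The vesicle dwells
# in firm contact (masks overlapping) for `contact_frames` frames and sits
# clearly separated (mask gap well above the touch tolerance) in the rest;
# the single transition step stays below the tracking search radius.
preset_single_track <- function(contact_frames) {
  n_frames <- 20L
  r_c <- footprint_radius(2)    # cluster sigma 2 px
  r_v <- footprint_radius(1.2)  # vesicle sigma 1.2 px
  d_in <- r_c + r_v - 2         # masks overlap by ~2 px: firm contact
  d_out <- d_in + 4.8           # mask gap ~2.8 px: firmly apart
  cy <- 32; cx <- 22
  off <- numeric(n_frames)
  if (contact_frames == 15) {
    # frames 1-5 approach from outside, frames 6-20 in contact
    off[1:5] <- d_out + 4.4 * (5 - (1:5))
    off[6:20] <- d_in
  } else {
    # frames 1-19 in contact, frame 20 steps out
    off[1:19] <- d_in
    off[20] <- d_out
  }
  path <- cbind(y = rep(cy, n_frames), x = cx + off)
  contact <- off <= d_in + 1e-9
  generator_params(
    mode = "tirf2d", field_shape = c(64, 64), pixel_pitch_xy = 0.1,
    frame_interval = 1, n_frames = n_frames, n_clusters = 1,
    cluster_sigma = 2, n_vesicles = 1,
    vesicle_recruitment_window = c(0, 0), vesicle_speed = 0,
    assoc_fraction = 1, dwell_prob = 0, flare_prob = 0, psf_sigma = 1.2,
    background = 0, read_noise_sd = 0, noise_free = TRUE, seed = 0,
    plant = list(
      cluster_positions = cbind(y = cy, x = cx),
      vesicle_paths = list(path),
      contact = matrix(contact, ncol = 1),
      expected = list(contact_frames = sum(contact),
                      lifetime = n_frames,
                      lifetime_fraction = sum(contact) / n_frames)))
}

# Deterministic single-ROI lag: cluster from frame 1; the vesicle centroid
# first comes within one pixel pitch of the cluster footprint at the 26th
# frame (25 intervals of 2 s = 50 s).
preset_lag50 <- function() {
  n_frames <- 40L
  r_c <- footprint_radius(2)
  cy <- 48; cx <- 24
  first_contact_frame <- 26L
  d_in <- r_c - 1.5     # centroid inside the cluster footprint
  d_far <- d_in + 4.8   # centroid > 1 px out AND mask gap > touch tolerance
  off <- numeric(n_frames)
  f <- seq_len(n_frames)
  off[f >= first_contact_frame] <- d_in
  pre <- f < first_contact_frame
  off[pre] <- pmin(d_far + 4 * (first_contact_frame - 1 - f[pre]), 55)
  path <- cbind(y = rep(cy, n_frames), x = cx + off)
  contact <- off <= d_in + 1e-9
  generator_params(
    mode = "tirf2d", field_shape = c(96, 96), pixel_pitch_xy = 0.1,
    frame_interval = 2, n_frames = n_frames, n_clusters = 1,
    cluster_sigma = 2, n_vesicles = 1,
    vesicle_recruitment_window = c(0, 0), vesicle_speed = 0,
    assoc_fraction = 1, dwell_prob = 0, flare_prob = 0, psf_sigma = 1.2,
    background = 0, read_noise_sd = 0, noise_free = TRUE, seed = 0,
    plant = list(
      cluster_positions = cbind(y = cy, x = cx),
      vesicle_paths = list(path),
      contact = matrix(contact, ncol = 1),
      expected = list(first_contact_frame = first_contact_frame,
                      first_contact_time = (first_contact_frame - 1) * 2,
                      lag_s = 50)))
}

# Twenty vesicles over 200 frames with moderate camera noise: 16 vesicles
# each orbit their own microcluster with one 20-frame excursion (fraction
# >= 0.80), 4 wander in interstitial space and never touch (fraction 0).
preset_paper_synapse <- function() {
  n_frames <- 200L
  grid_y <- 22 + (0:3) * 39
  grid_x <- 25 + (0:4) * 28
  clusters <- as.matrix(expand.grid(y = grid_y, x = grid_x))
  r_c <- footprint_radius(2); r_v <- footprint_radius(1.2)
  exc_d <- r_c + r_v + 4
  anchors <- rbind(c(41.5, 39), c(41.5, 123), c(119.5, 39), c(119.5, 123))
  generator_params(
    mode = "tirf2d", field_shape = c(160, 160), pixel_pitch_xy = 0.1,
    frame_interval = 1, n_frames = n_frames, n_clusters = 20,
    cluster_sigma = 2, n_vesicles = 20,
    vesicle_recruitment_window = c(0, 0), vesicle_speed = 0.25,
    assoc_fraction = 0.8, dwell_prob = 1, flare_prob = 0, psf_sigma = 1.2,
    background = 100, read_noise_sd = 3, noise_free = FALSE, seed = 1,
    plant = list(
      cluster_positions = clusters,
      synapse_plan = list(n_high = 16L, n_low = 4L, orbit_radius = 1,
                          excursion_length = 20L, excursion_dist = exc_d,
                          excursion_window = c(40L, 160L),
                          anchors = anchors, walk_step = 1.2,
                          walk_radius = 8, transition_step = 3.5),
      expected = list(n_high = 16L, n_low = 4L,
                      association_pct = 100 * 16 / 20)))
}

preset_two_phase <- function(mode) {
  if (mode == "tirf2d") {
    generator_params(
      mode = "tirf2d", field_shape = c(128, 128), pixel_pitch_xy = 0.1,
      frame_interval = 1.5, n_frames = 140, n_clusters = 10,
      cluster_sigma = 2, cluster_decay_half_life = 200,
      n_vesicles = 12, vesicle_recruitment_window = c(45, 60),
      vesicle_speed = 0.25, assoc_fraction = 0.8, dwell_prob = 0.7,
      dwell_duration = 15, flare_prob = 0.25, flare_amplitude = 2.5,
      flare_duration = 4, psf_sigma = 1.2, background = 100,
      read_noise_sd = 3, noise_free = FALSE, seed = 1,
      plant = list(expected = list(recruitment_window_s = c(45, 60))))
  } else {
    generator_params(
      mode = "llsm3d", field_shape = c(18, 80, 80), pixel_pitch_xy = 0.1,
      z_step = 0.25, frame_interval = 1.5, n_frames = 140, n_clusters = 8,
      cluster_sigma = 2, cluster_decay_half_life = 200,
      n_vesicles = 10, vesicle_recruitment_window = c(45, 60),
      vesicle_speed = 0.25, assoc_fraction = 0.8, dwell_prob = 0.7,
      dwell_duration = 15, flare_prob = 0.25, flare_amplitude = 2.5,
      flare_duration = 4, psf_sigma = 1.2, background = 100,
      read_noise_sd = 3, noise_free = FALSE, seed = 1,
      plant = list(plane_z = 4, z_high = 16, descent_frames = 4,
                   expected = list(recruitment_window_s = c(45, 60))))
  }
}

#' Simulate a two-phase synapse time-lapse with ground truth
#'
#' Renders the cluster and vesicle channels of the generative model defined
#' by \code{params} (see \code{\link{generator_params}}) and returns the
#' images together with complete per-frame ground truth. Identical
#' \code{(params, seed)} give bit-identical output.
#'
#' @param params a \code{generator_params}, typically from
#'   \code{\link{make_preset}}.
#' @param seed integer seed; defaults to \code{params$seed}.
#' @return list of class \code{simulation}: \code{images} (an
#'   \code{\link{image_series}} with channels \code{cluster}, \code{vesicle}),
#'   \code{truth} (lists \code{vesicles}, \code{vesicle_frames},
#'   \code{clusters}, \code{flares}), and \code{params}.
#' @export
simulate_timelapse <- function(params, seed = NULL) {
  stopifnot(inherits(params, "generator_params"))
  if (is.null(seed)) seed <- params$seed
  with_seed(seed, simulate_impl(params, seed))
}

simulate_impl <- function(params, seed) {
  p <- params
  nd <- length(p$field_shape)
  shape <- p$field_shape
  xy_shape <- shape[(nd - 1):nd]
  margin <- 4 * p$cluster_sigma + 2
  if (any(xy_shape < 2 * margin + 1) && p$n_clusters > 0)
    stop("field too small to contain the requested objects")

  # --- cluster positions -------------------------------------------------
  if (!is.null(p$plant$cluster_positions)) {
    cl_xy <- p$plant$cluster_positions
    if (!is.null(p$plant$synapse_plan)) { # small seeded jitter on the grid
      cl_xy <- cl_xy + matrix(stats::runif(length(cl_xy), -2, 2),
                              ncol = 2)
    }
  } else if (p$n_clusters > 0) {
    cl_xy <- place_points(p$n_clusters, xy_shape, margin,
                          min_sep = 8 * p$cluster_sigma + 4)
  } else {
    cl_xy <- matrix(numeric(0), 0, 2)
  }

  # --- vesicle trajectories ---------------------------------------------
  step_px <- p$vesicle_speed * p$frame_interval / p$pixel_pitch_xy
  rec_time <- stats::runif(p$n_vesicles, p$vesicle_recruitment_window[1],
                           p$vesicle_recruitment_window[2])
  rec_frame <- pmin(as.integer(ceiling(rec_time / p$frame_interval)) + 1L,
                    p$n_frames)
  n_assoc <- round(p$assoc_fraction * p$n_vesicles)
  assoc <- seq_len(p$n_vesicles) <= n_assoc

  paths <- vector("list", p$n_vesicles)   # n_frames x 2 (y, x), NA invisible
  zpos <- vector("list", p$n_vesicles)    # n_frames z (llsm3d)
  flares <- data.frame(vesicle = integer(0), start_frame = integer(0),
                       duration = integer(0))
  plan <- p$plant$synapse_plan
  for (v in seq_len(p$n_vesicles)) {
    if (!is.null(p$plant$vesicle_paths)) {
      paths[[v]] <- p$plant$vesicle_paths[[v]]
    } else if (!is.null(plan)) {
      paths[[v]] <- synapse_plan_path(v, plan, cl_xy, p$n_frames)
    } else if (assoc[v] && nrow(cl_xy) > 0) {
      res <- assoc_path(cl_xy, rec_frame[v], p$n_frames, step_px,
                        p$dwell_prob, p$dwell_duration, p$flare_prob,
                        p$flare_duration, visible_before = p$mode == "llsm3d")
      paths[[v]] <- res$pos
      if (nrow(res$flares)) {
        res$flares$vesicle <- v
        flares <- rbind(flares, res$flares[, c("vesicle", "start_frame",
                                               "duration")])
      }
    } else {
      paths[[v]] <- walk_path(xy_shape, rec_frame[v], p$n_frames, step_px,
                              visible_before = p$mode == "llsm3d")
    }
    if (p$mode == "llsm3d") {
      zh <- p$plant$z_high; pz <- p$plant$plane_z
      df <- p$plant$descent_frames
      z <- rep(zh, p$n_frames)
      if (assoc[v]) {
        rf <- rec_frame[v]
        for (t in seq_len(p$n_frames)) {
          if (t >= rf) z[t] <- pz
          else if (t > rf - df) z[t] <- zh - (zh - pz) * (t - (rf - df)) / df
        }
      }
      zpos[[v]] <- z
    }
  }

  # --- ground truth ------------------------------------------------------
  touch_d_um <- (footprint_radius(p$cluster_sigma) +
                 footprint_radius(p$psf_sigma) + 1) * p$pixel_pitch_xy
  vf <- vesicle_truth_frames(p, paths, zpos, cl_xy, touch_d_um)
  if (!is.null(p$plant$contact)) {
    for (v in seq_len(p$n_vesicles)) {
      sel <- vf$vesicle == v
      vf$contact[sel] <- p$plant$contact[vf$frame[sel], v]
    }
  }
  ves_summary <- do.call(rbind, lapply(seq_len(p$n_vesicles), function(v) {
    s <- vf[vf$vesicle == v & vf$visible, ]
    data.frame(vesicle = v, associated = assoc[v],
               recruitment_time_s = if (p$vesicle_recruitment_window[2] > 0)
                 rec_time[v] else 0,
               n_visible = nrow(s),
               lifetime_fraction = if (nrow(s)) mean(s$contact) else NA_real_)
  }))
  truth <- list(vesicles = ves_summary, vesicle_frames = vf,
                clusters = data.frame(cluster = seq_len(nrow(cl_xy)),
                                      y_px = cl_xy[, 1], x_px = cl_xy[, 2],
                                      appearance_frame = 1L),
                flares = flares)

  # --- rendering ---------------------------------------------------------
  dims <- c(p$n_frames, 2L, shape)
  data <- array(0, dim = dims)
  flare_r <- 3 * p$psf_sigma
  for (t in seq_len(p$n_frames)) {
    decay <- if (is.null(p$cluster_decay_half_life)) 1 else
      2^(-(t - 1) / p$cluster_decay_half_life)
    cl_frame <- array(0, dim = shape)
    for (i in seq_len(nrow(cl_xy))) {
      center <- if (nd == 2) cl_xy[i, ] else c(p$plant$plane_z, cl_xy[i, ])
      cl_frame <- add_gaussian_spot(cl_frame, center, p$cluster_sigma,
                                    p$cluster_amplitude * decay)
    }
    ve_frame <- array(0, dim = shape)
    for (v in seq_len(p$n_vesicles)) {
      pos <- paths[[v]][t, ]
      if (any(is.na(pos))) next
      center <- if (nd == 2) pos else c(zpos[[v]][t], pos)
      ve_frame <- add_gaussian_spot(ve_frame, center, p$psf_sigma,
                                    p$vesicle_amplitude)
    }
    if (nrow(flares)) {
      for (i in seq_len(nrow(flares))) {
        fl <- flares[i, ]
        if (t < fl$start_frame || t >= fl$start_frame + fl$duration) next
        pos <- paths[[fl$vesicle]][t, ]
        if (any(is.na(pos))) next
        center <- if (nd == 2) pos else c(zpos[[fl$vesicle]][t], pos)
        reg <- spot_region(shape, center, flare_r)
        cl_frame[reg] <- cl_frame[reg] * p$flare_amplitude
        ve_frame[reg] <- ve_frame[reg] * p$flare_amplitude
      }
    }
    for (ch in 1:2) {
      signal <- if (ch == 1) cl_frame else ve_frame
      if (p$noise_free) {
        img <- signal + p$background
      } else {
        img <- stats::rpois(length(signal), as.numeric(signal) + p$background) +
          stats::rnorm(length(signal), 0, p$read_noise_sd)
        img <- array(img, dim = shape)
      }
      if (nd == 2) data[t, ch, , ] <- img else data[t, ch, , , ] <- img
    }
  }
  images <- image_series(data, pixel_pitch = p$pixel_pitch_xy,
                         frame_interval = p$frame_interval,
                         z_step = p$z_step,
                         channels = c("cluster", "vesicle"))
  structure(list(images = images, truth = truth, params = p, seed = seed),
            class = "simulation")
}

#' @export
print.simulation <- function(x, ...) {
  cat("<simulation>", x$params$mode, "|", x$params$n_frames, "frames |",
      nrow(x$truth$clusters), "clusters,", nrow(x$truth$vesicles),
      "vesicles |", nrow(x$truth$flares), "flares | seed", x$seed, "\n")
  invisible(x)
}

# Rejection-sample point positions with a minimum separation and margin.
place_points <- function(n, xy_shape, margin, min_sep) {
  if (any(xy_shape - 2 * margin <= 0))
    stop("field too small to contain the requested objects")
  pts <- matrix(numeric(0), 0, 2)
  tries <- 0
  while (nrow(pts) < n) {
    cand <- c(stats::runif(1, margin, xy_shape[1] - margin),
              stats::runif(1, margin, xy_shape[2] - margin))
    if (nrow(pts) == 0 ||
        min(sqrt(rowSums(sweep(pts, 2, cand)^2))) >= min_sep) {
      pts <- rbind(pts, cand)
    }
    tries <- tries + 1
    if (tries > 5000 * n)
      stop("field too small to contain the requested objects")
  }
  unname(pts)
}

# Directed cluster-to-cluster path with dwells and optional flares.
assoc_path <- function(cl_xy, rec_frame, n_frames, step_px, dwell_prob,
                       dwell_duration, flare_prob, flare_duration,
                       visible_before = FALSE) {
  pos <- matrix(NA_real_, n_frames, 2)
  fl <- data.frame(start_frame = integer(0), duration = integer(0))
  start <- sample.int(nrow(cl_xy), 1)
  cur <- cl_xy[start, ]
  if (visible_before && rec_frame > 1) {
    pos[seq_len(rec_frame - 1), ] <- matrix(cur, rec_frame - 1, 2,
                                            byrow = TRUE)
  }
  if (rec_frame > n_frames) return(list(pos = pos, flares = fl))
  target <- start
  dwell_left <- 0L
  maybe_flare <- function(t) {
    if (stats::runif(1) < flare_prob && t + flare_duration - 1 <= n_frames) {
      fl[nrow(fl) + 1L, ] <<- list(t, flare_duration)
    }
  }
  # arriving at the synapse counts as the first cluster visit
  if (stats::runif(1) < dwell_prob) {
    dwell_left <- dwell_duration
    maybe_flare(rec_frame)
  }
  for (t in rec_frame:n_frames) {
    pos[t, ] <- cur
    if (dwell_left > 0L) {
      dwell_left <- dwell_left - 1L
      next
    }
    if (target == start || all(abs(cur - cl_xy[target, ]) < 1e-9)) {
      # pick a fresh destination
      target <- if (nrow(cl_xy) > 1)
        sample(setdiff(seq_len(nrow(cl_xy)), target), 1) else target
    }
    dest <- cl_xy[target, ]
    delta <- dest - cur
    dist <- sqrt(sum(delta^2))
    if (dist <= step_px) {
      cur <- dest
      start <- 0L # mark as travelling; arrival handled below
      if (stats::runif(1) < dwell_prob) {
        dwell_left <- dwell_duration
        if (t + 1 <= n_frames) maybe_flare(t + 1L)
      }
    } else {
      cur <- cur + delta / dist * step_px
    }
  }
  list(pos = pos, flares = fl)
}

# Reflected random walk within the field.
walk_path <- function(xy_shape, rec_frame, n_frames, step_px,
                      visible_before = FALSE) {
  pos <- matrix(NA_real_, n_frames, 2)
  margin <- 6
  cur <- c(stats::runif(1, margin, xy_shape[1] - margin),
           stats::runif(1, margin, xy_shape[2] - margin))
  from <- if (visible_before) 1L else min(rec_frame, n_frames)
  for (t in from:n_frames) {
    pos[t, ] <- cur
    ang <- stats::runif(1, 0, 2 * pi)
    cand <- cur + step_px * c(sin(ang), cos(ang))
    for (a in 1:2) {
      if (cand[a] < margin) cand[a] <- 2 * margin - cand[a]
      if (cand[a] > xy_shape[a] - margin)
        cand[a] <- 2 * (xy_shape[a] - margin) - cand[a]
    }
    cur <- cand
  }
  pos
}

# Planted paths for the population-association preset: vesicles 1..n_high
# orbit cluster v with one excursion block; the rest wander around
# interstitial anchors and never approach a cluster.
synapse_plan_path <- function(v, plan, cl_xy, n_frames) {
  pos <- matrix(NA_real_, n_frames, 2)
  if (v <= plan$n_high) {
    center <- cl_xy[v, ]
    phase <- stats::runif(1, 0, 2 * pi)
    exc_start <- sample(seq(plan$excursion_window[1],
                            plan$excursion_window[2]), 1)
    exc_dir <- if (v %% 2 == 0) c(0, 1) else c(0, -1)
    exc_point <- center + exc_dir * plan$excursion_dist
    for (t in seq_len(n_frames)) {
      anchor <- if (t >= exc_start &&
                    t < exc_start + plan$excursion_length)
        exc_point else
          center + plan$orbit_radius * c(sin(phase + t / 8),
                                         cos(phase + t / 8))
      if (t == 1) {
        pos[t, ] <- anchor
      } else {
        delta <- anchor - pos[t - 1, ]
        d <- sqrt(sum(delta^2))
        pos[t, ] <- if (d <= plan$transition_step) anchor else
          pos[t - 1, ] + delta / d * plan$transition_step
      }
    }
  } else {
    anchor <- plan$anchors[v - plan$n_high, ]
    cur <- anchor
    for (t in seq_len(n_frames)) {
      pos[t, ] <- cur
      ang <- stats::runif(1, 0, 2 * pi)
      cand <- cur + plan$walk_step * c(sin(ang), cos(ang))
      if (sqrt(sum((cand - anchor)^2)) > plan$walk_radius) cand <- cur
      cur <- cand
    }
  }
  pos
}

# Per-frame truth table: visibility and the planted contact flag (physical
# center-to-center distance against the nominal touch distance).
vesicle_truth_frames <- function(p, paths, zpos, cl_xy, touch_d_um) {
  nd <- length(p$field_shape)
  rows <- vector("list", p$n_vesicles)
  for (v in seq_len(p$n_vesicles)) {
    pos <- paths[[v]]
    visible <- !is.na(pos[, 1])
    contact <- rep(FALSE, p$n_frames)
    if (nrow(cl_xy) > 0) {
      for (t in which(visible)) {
        dx_um <- sweep(cl_xy, 2, pos[t, ])
        d2 <- rowSums((dx_um * p$pixel_pitch_xy)^2)
        if (nd == 3) {
          dz <- (zpos[[v]][t] - p$plant$plane_z) * p$z_step
          d2 <- d2 + dz^2
        }
        contact[t] <- sqrt(min(d2)) <= touch_d_um
      }
    }
    rows[[v]] <- data.frame(vesicle = v, frame = seq_len(p$n_frames),
                            y_px = pos[, 1], x_px = pos[, 2],
                            z_px = if (nd == 3) zpos[[v]] else NA_real_,
                            visible = visible, contact = contact)
  }
  do.call(rbind, rows)
}

# Add an isotropic Gaussian spot (peak `amplitude`) at a continuous center.
add_gaussian_spot <- function(frame, center, sigma, amplitude) {
  d <- dim(frame)
  nd <- length(d)
  r <- ceiling(4 * sigma)
  idx <- lapply(seq_len(nd), function(a) {
    lo <- max(1L, floor(center[a] - r)); hi <- min(d[a], ceiling(center[a] + r))
    if (lo > hi) integer(0) else lo:hi
  })
  if (any(lengths(idx) == 0)) return(frame)
  g <- lapply(seq_len(nd), function(a)
    exp(-(idx[[a]] - center[a])^2 / (2 * sigma^2)))
  spot <- amplitude * Reduce(`%o%`, g)
  if (nd == 2) {
    frame[idx[[1]], idx[[2]]] <- frame[idx[[1]], idx[[2]]] + spot
  } else {
    frame[idx[[1]], idx[[2]], idx[[3]]] <-
      frame[idx[[1]], idx[[2]], idx[[3]]] + spot
  }
  frame
}

# Linear indices of the Euclidean ball around a center (flare footprint).
spot_region <- function(shape, center, radius) {
  nd <- length(shape)
  r <- ceiling(radius)
  idx <- lapply(seq_len(nd), function(a) {
    lo <- max(1L, floor(center[a] - r)); hi <- min(shape[a], ceiling(center[a] + r))
    lo:hi
  })
  grid <- as.matrix(do.call(expand.grid, idx))
  d2 <- rowSums(sweep(grid, 2, center)^2)
  grid <- grid[d2 <= radius^2, , drop = FALSE]
  lin <- grid[, 1]
  if (nd >= 2) lin <- lin + (grid[, 2] - 1) * shape[1]
  if (nd == 3) lin <- lin + (grid[, 3] - 1) * shape[1] * shape[2]
  lin
}
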