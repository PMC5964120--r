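# Shared fixture builders. Simulations of the named presets are cached per
# session so several test files can reuse the same deterministic run.

.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(preset, seed = NULL) {
  key <- paste0(preset, "_", if (is.null(seed)) "default" else seed)
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- simulate_timelapse(make_preset(preset), seed = seed)
  }
  .sim_cache[[key]]
}

cached_pipeline <- function(preset, seed = NULL) {
  key <- paste0("pipe_", preset, "_", if (is.null(seed)) "default" else seed)
  if (is.null(.sim_cache[[key]])) {
    sim <- cached_sim(preset, seed)
    .sim_cache[[key]] <- run_pipeline(sim$images)
  }
  .sim_cache[[key]]
}

# A frame with Gaussian spots at the given (y, x) centers.
spot_frame <- function(shape, centers, sigma = 1.5, amplitude = 100,
                       offset = 0) {
  f <- array(offset, dim = shape)
  for (i in seq_len(nrow(centers))) {
    f <- synaptrack:::add_gaussian_spot(f, centers[i, ], sigma, amplitude)
  }
  f
}

# Labeled objects built from small solid squares at integer positions, for
# tracking fixtures where exact centroids matter.
square_objects <- function(shape, centers, half = 1, frame_index = 1) {
  f <- matrix(0, shape[1], shape[2])
  for (i in seq_len(nrow(centers))) {
    ys <- (centers[i, 1] - half):(centers[i, 1] + half)
    xs <- (centers[i, 2] - half):(centers[i, 2] + half)
    f[ys, xs] <- 100
  }
  segment_frame(f, 50, min_size = 1, frame_index = frame_index, channel = 1L)
}

# Exhaustive frame-to-frame optimal assignment (minimum total displacement
# with per-link cutoff), the oracle for the greedy tracker on tiny
# instances. Returns per-object track memberships in link order.
oracle_link <- function(centroid_list, max_disp) {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  n_frames <- length(centroid_list)
  ids <- list()
  ids[[1]] <- seq_len(nrow(centroid_list[[1]]))
  next_id <- nrow(centroid_list[[1]])
  for (t in 2:n_frames) {
    prev <- centroid_list[[t - 1]]
    cur <- centroid_list[[t]]
    np <- nrow(prev); nc <- nrow(cur)
    # try all injective maps cur -> prev (padded with "new track" = 0)
    cand <- perms(c(seq_len(np), rep(0L, nc)))
    best <- NULL; best_cost <- Inf
    seen <- character(0)
    for (p in cand) {
      asg <- p[seq_len(nc)]
      key <- paste(asg, collapse = ",")
      if (key %in% seen) next
      seen <- c(seen, key)
      cost <- 0; ok <- TRUE
      for (j in seq_len(nc)) {
        if (asg[j] == 0L) { cost <- cost + max_disp * 2 } else {
          dd <- sqrt(sum((cur[j, ] - prev[asg[j], ])^2))
          if (dd > max_disp) { ok <- FALSE; break }
          cost <- cost + dd
        }
      }
      if (ok && cost < best_cost) { best_cost <- cost; best <- asg }
    }
    new_ids <- integer(nc)
    for (j in seq_len(nc)) {
      if (best[j] > 0L) new_ids[j] <- ids[[t - 1]][best[j]]
      else { next_id <- next_id + 1L; new_ids[j] <- next_id }
    }
    ids[[t]] <- new_ids
  }
  ids
}
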