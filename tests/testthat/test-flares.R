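test_that("RFI normalization has mean exactly 1 per channel", {
  res <- cached_pipeline("track145")
  sim <- cached_sim("track145")
  rfi <- object_rfi_series(res$tracks[[1]], sim$images,
                          res$detections$vesicle)
  expect_equal(mean(rfi$cluster), 1)
  expect_equal(mean(rfi$vesicle), 1)
  # constant image, constant mask -> RFI identically 1
  a <- array(50, dim = c(4, 2, 20, 20))
  s <- image_series(a, 0.1, 1, channels = c("cluster", "vesicle"))
  det <- lapply(1:4, function(t) {
    m <- matrix(0, 20, 20); m[8:10, 8:10] <- 100
    segment_frame(m, 50, min_size = 1, frame_index = t, channel = 2L)
  })
  tr <- link_tracks(det, max_disp = 5, max_gap = 0)[[1]]
  rfi2 <- object_rfi_series(tr, s, det)
  expect_equal(rfi2$cluster, rep(1, 4))
  # one frame at double intensity among 9 constant: 2 / 1.1
  a3 <- array(50, dim = c(10, 2, 20, 20)); a3[4, , , ] <- 100
  s3 <- image_series(a3, 0.1, 1, channels = c("cluster", "vesicle"))
  det3 <- lapply(1:10, function(t) {
    m <- matrix(0, 20, 20); m[8:10, 8:10] <- 100
    segment_frame(m, 50, min_size = 1, frame_index = t, channel = 2L)
  })
  tr3 <- link_tracks(det3, max_disp = 5, max_gap = 0)[[1]]
  rfi3 <- object_rfi_series(tr3, s3, det3)
  expect_equal(rfi3$vesicle[4], 2 / 1.1, tolerance = 1e-12)
})

test_that("flare detection needs a coincident two-channel increase", {
  n <- 30
  mk <- function(a, b) {
    out <- data.frame(frame = 1:n, cluster = a, vesicle = b)
    class(out) <- c("rfi_series", "data.frame")
    out
  }
  base <- 1 + 0.02 * sin(1:n)
  expect_equal(nrow(detect_flares(mk(base, base))), 0)
  step <- base; step[12:16] <- base[12:16] + 5 * stats::mad(base)
  ev <- detect_flares(mk(step, step))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start_frame, 12)
  expect_equal(ev$duration, 5)
  expect_gt(ev$peak_cluster, 1)
  # an increase in one channel only is not a flare
  expect_equal(nrow(detect_flares(mk(step, base))), 0)
  # short tracks are rejected
  expect_error(detect_flares(mk(base, base)[1:5, ]), "short")
  # invariance to positive affine rescaling of either channel
  ev2 <- detect_flares(mk(3 * step + 2, 0.5 * step - 0.2))
  expect_equal(ev2$start_frame, ev$start_frame)
  expect_equal(ev2$duration, ev$duration)
})

test_that("speeds partition into at-flare and away-from-flare classes", {
  # stationary over frames 4-8; the flare spans 5-7, so every step with an
  # endpoint in the flare has zero displacement
  cen <- rbind(cbind(10, 10 + (1:3) * 2), cbind(10, 16)[rep(1, 5), ],
               cbind(10, 16 + (1:4) * 2))
  tr <- list(id = 1L, channel = 2L, frame = 1:12, label = rep(1L, 12),
             centroid = cen, intensity = rep(1, 12), size = rep(9L, 12))
  class(tr) <- "track"
  fl <- data.frame(start_frame = 5L, duration = 3L)
  sp <- speed_partition(tr, fl, spacing = c(0.1, 0.1), frame_interval = 1)
  expect_equal(sp$mean_at, 0, tolerance = 1e-12)
  expect_gt(sp$mean_away, 0)
  none <- speed_partition(tr, fl[0, ], c(0.1, 0.1), 1)
  expect_length(none$at, 0)
  expect_length(none$away, 11)
})

test_that("planted flares are recovered with high sensitivity across seeds", {
  p <- generator_params(field_shape = c(64, 64), n_frames = 50,
                        frame_interval = 1, n_clusters = 2, n_vesicles = 1,
                        vesicle_recruitment_window = c(0, 0),
                        vesicle_speed = 0.45, dwell_prob = 1,
                        dwell_duration = 16, flare_prob = 1,
                        flare_amplitude = 2.5, flare_duration = 4,
                        background = 100, read_noise_sd = 3)
  hits <- 0; planted <- 0; false_events <- 0; tracks_seen <- 0
  for (seed in 1:10) {
    sim <- simulate_timelapse(p, seed = seed)
    if (nrow(sim$truth$flares) == 0) next
    det_ve <- detect_channel(sim$images, "vesicle", spot_sigma = 1.2)
    tracks <- link_tracks(det_ve)
    main <- tracks[[which.max(vapply(tracks, track_lifetime, 1L))]]
    rfi <- object_rfi_series(main, sim$images, det_ve)
    ev <- detect_flares(rfi)
    tracks_seen <- tracks_seen + 1
    truth <- sim$truth$flares
    planted <- planted + nrow(truth)
    matched <- rep(FALSE, nrow(ev))
    for (i in seq_len(nrow(truth))) {
      near <- which(!matched & abs(ev$start_frame - truth$start_frame[i]) <= 2)
      if (length(near)) { hits <- hits + 1; matched[near[1]] <- TRUE }
    }
    false_events <- false_events + sum(!matched)
  }
  expect_gt(planted, 5)
  expect_gte(hits / planted, 0.9)
  expect_lte(false_events / tracks_seen, 1)
})

test_that("vesicles slow down at planted flare dwells", {
  p <- generator_params(field_shape = c(64, 64), n_frames = 50,
                        frame_interval = 1, n_clusters = 2, n_vesicles = 1,
                        vesicle_recruitment_window = c(0, 0),
                        vesicle_speed = 0.45, dwell_prob = 1,
                        dwell_duration = 16, flare_prob = 1,
                        flare_amplitude = 2.5, flare_duration = 4,
                        background = 100, read_noise_sd = 3)
  sim <- simulate_timelapse(p, seed = 2)
  det_ve <- detect_channel(sim$images, "vesicle", spot_sigma = 1.2)
  tracks <- link_tracks(det_ve)
  main <- tracks[[which.max(vapply(tracks, track_lifetime, 1L))]]
  rfi <- object_rfi_series(main, sim$images, det_ve)
  ev <- detect_flares(rfi)
  sp <- speed_partition(main, ev, spacing = c(0.1, 0.1), frame_interval = 1)
  expect_true(nrow(ev) >= 1)
  expect_lt(sp$mean_at, sp$mean_away)
})
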