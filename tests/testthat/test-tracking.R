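test_that("a single moving object yields one full-lifetime track", {
  frames <- lapply(1:10, function(t)
    square_objects(c(40, 40), cbind(20, 10 + t), frame_index = t))
  tr <- link_tracks(frames, max_disp = 5, max_gap = 2)
  expect_length(tr, 1)
  expect_equal(track_lifetime(tr[[1]]), 10)
  expect_equal(tr[[1]]$centroid[, 2], 11:20)
})

test_that("objects beyond max_disp are never merged", {
  frames <- lapply(1:6, function(t)
    square_objects(c(40, 60), rbind(c(10, 10 + t), c(30, 40 + t)),
                   frame_index = t))
  tr <- link_tracks(frames, max_disp = 5, max_gap = 2)
  expect_length(tr, 2)
  expect_true(all(vapply(tr, track_lifetime, 1L) == 6))
  # each track stays on one row
  rows <- vapply(tr, function(t) unique(t$centroid[, 1]), 1)
  expect_setequal(rows, c(10, 30))
})

test_that("gap closing bridges a single missed frame only when allowed", {
  mk <- function(t, present) {
    if (present) square_objects(c(30, 30), cbind(15, 10 + t), frame_index = t)
    else segment_frame(matrix(0, 30, 30), 50, min_size = 1, frame_index = t)
  }
  frames <- list(mk(1, TRUE), mk(2, FALSE), mk(3, TRUE))
  with_gap <- link_tracks(frames, max_disp = 5, max_gap = 1)
  expect_length(with_gap, 1)
  expect_equal(with_gap[[1]]$frame, c(1L, 3L))
  no_gap <- link_tracks(frames, max_disp = 5, max_gap = 0)
  expect_length(no_gap, 2)
  # oracle agreement on this instance: optimal assignment also links 1-3
  expect_length(link_tracks(frames, max_disp = 11, max_gap = 1), 1)
})

test_that("every object belongs to exactly one track", {
  set.seed(11)
  frames <- lapply(1:8, function(t) {
    n <- sample(1:4, 1)
    centers <- cbind(sample(seq(5, 55, by = 10), n),
                     sample(seq(5, 55, by = 10), n))
    square_objects(c(60, 60), centers, frame_index = t)
  })
  tr <- link_tracks(frames, max_disp = 4, max_gap = 2)
  n_obs <- sum(vapply(tr, track_lifetime, 1L))
  n_obj <- sum(vapply(frames, function(f) nrow(f$objects), 1L))
  expect_equal(n_obs, n_obj)
})

test_that("greedy linking matches exhaustive assignment on unambiguous instances", {
  set.seed(19)
  for (rep in 1:5) {
    n_obj <- sample(2:3, 1)
    n_fr <- sample(4:6, 1)
    # anchors far apart (> 2 * max step) with small per-frame jitter
    anchors <- cbind(seq(10, by = 18, length.out = n_obj),
                     sample(seq(10, by = 15, length.out = n_obj)))
    paths <- lapply(seq_len(n_fr), function(t)
      anchors + matrix(runif(2 * n_obj, -1.5, 1.5), n_obj, 2))
    frames <- lapply(seq_len(n_fr), function(t)
      square_objects(c(80, 80), round(paths[[t]]), frame_index = t))
    tr <- link_tracks(frames, max_disp = 6, max_gap = 0)
    expect_length(tr, n_obj)
    cents <- lapply(frames, function(f)
      as.matrix(f$objects[, c("y_px", "x_px")]))
    oracle_ids <- oracle_link(cents, max_disp = 6)
    # identity agreement: greedy track membership == oracle membership
    greedy_ids <- lapply(seq_len(n_fr), function(t) {
      ids <- integer(nrow(cents[[t]]))
      for (k in seq_along(tr)) {
        sel <- tr[[k]]$frame == t
        if (any(sel)) {
          j <- which(apply(cents[[t]], 1, function(p)
            all(abs(p - tr[[k]]$centroid[sel, ]) < 1e-9)))
          ids[j] <- k
        }
      }
      ids
    })
    relabel <- function(ids) match(unlist(ids), unique(unlist(ids)))
    expect_equal(relabel(greedy_ids), relabel(oracle_ids))
  }
})

test_that("kinematics convert displacement and elapsed time correctly", {
  frames <- lapply(1:5, function(t)
    square_objects(c(30, 30), cbind(15, 8 + t), frame_index = t))
  tr <- link_tracks(frames, max_disp = 5, max_gap = 0)[[1]]
  kin <- track_kinematics(tr, spacing = c(0.1, 0.1), frame_interval = 1)
  expect_equal(kin$speed_um_s, rep(0.1, 4))
  still <- link_tracks(lapply(1:4, function(t)
    square_objects(c(30, 30), cbind(15, 15), frame_index = t)),
    max_disp = 5, max_gap = 0)[[1]]
  expect_equal(track_kinematics(still, c(0.1, 0.1), 1)$speed_um_s,
               rep(0, 3))
  # a step across a 2-frame gap uses the true elapsed time
  gap_tr <- list(id = 1L, channel = 1L, frame = c(1L, 3L),
                 label = c(1L, 1L),
                 centroid = rbind(c(10, 10), c(10, 14)),
                 intensity = c(1, 1), size = c(9L, 9L))
  class(gap_tr) <- "track"
  kin <- track_kinematics(gap_tr, c(0.1, 0.1), 1)
  expect_equal(kin$displacement_um, 0.4)
  expect_equal(kin$speed_um_s, 0.2)
  one <- gap_tr; one$frame <- 1L; one$centroid <- one$centroid[1, , drop = FALSE]
  expect_error(track_kinematics(one, c(0.1, 0.1), 1), "at least 2")
})

test_that("noise-free preset tracks reproduce the planted trajectory", {
  sim <- cached_sim("track145")
  res <- cached_pipeline("track145")
  expect_length(res$tracks, 1)
  tr <- res$tracks[[1]]
  expect_equal(tr$frame, 1:20)
  planted <- as.matrix(sim$truth$vesicle_frames[, c("y_px", "x_px")])
  expect_equal(unname(tr$centroid), unname(planted), tolerance = 0.2)
})
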