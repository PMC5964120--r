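test_that("distance field matches hand-computed geometry", {
  lab <- matrix(0L, 12, 12); lab[6, 6] <- 1L
  f <- cluster_distance_field(lab, spacing = c(0.1, 0.1))
  expect_equal(f[6, 6], 0)
  expect_equal(f[6, 7], 0.1)      # face neighbour
  expect_equal(f[9, 10], 0.5)     # (3, 4) offset: 3-4-5 triangle
  expect_warning(empty <- cluster_distance_field(matrix(0L, 5, 5), c(1, 1)),
                 "no cluster")
  expect_true(all(is.infinite(empty)))
})

test_that("distance field equals brute force on small images", {
  set.seed(23)
  for (rep in 1:4) {
    d <- sample(8:32, 2)
    sp <- runif(2, 0.05, 0.3)
    lab <- matrix(as.integer(runif(prod(d)) < 0.05), d[1], d[2])
    if (!any(lab > 0)) lab[3, 3] <- 1L
    f <- cluster_distance_field(lab, sp)
    cl <- arrayInd(which(lab > 0), d)
    for (i in sample(prod(d), 25)) {
      p <- arrayInd(i, d)
      brute <- min(sqrt(((cl[, 1] - p[1]) * sp[1])^2 +
                        ((cl[, 2] - p[2]) * sp[2])^2))
      expect_equal(f[i], brute, tolerance = 1e-12)
    }
  }
  # anisotropic 3-d
  d3 <- c(7, 9, 8); sp3 <- c(0.25, 0.1, 0.1)
  lab3 <- array(0L, d3); lab3[2, 3, 4] <- 1L; lab3[6, 7, 2] <- 1L
  f3 <- cluster_distance_field(lab3, sp3)
  cl3 <- arrayInd(which(lab3 > 0), d3)
  for (i in sample(prod(d3), 30)) {
    p <- arrayInd(i, d3)
    brute <- min(sqrt(colSums((t(cl3) - as.vector(p))^2 * sp3^2)))
    expect_equal(f3[i], brute, tolerance = 1e-12)
  }
})

test_that("distance series sample the field at observed centroids", {
  lab <- matrix(0L, 30, 30); lab[10:14, 10:14] <- 1L
  field <- cluster_distance_field(lab, c(0.1, 0.1))
  inside <- list(id = 1L, channel = 2L, frame = 1:3, label = rep(1L, 3),
                 centroid = rbind(c(12, 12), c(11, 13), c(12.4, 11.8)),
                 intensity = rep(1, 3), size = rep(4L, 3))
  class(inside) <- "track"
  s <- vesicle_distance_series(inside, list(field, field, field),
                               frame_times = c(0, 1, 2))
  expect_equal(s$distance_um, c(0, 0, 0))
  away <- inside; away$centroid <- rbind(c(20, 12), c(20, 12), c(20, 12))
  s2 <- vesicle_distance_series(away, list(field, field, field), 0:2)
  expect_equal(s2$distance_um, rep(0.6, 3)) # constant for a static pair
  out <- inside; out$centroid[2, ] <- c(200, 5)
  expect_error(vesicle_distance_series(out, list(field, field, field), 0:2),
               "outside")
  expect_error(vesicle_distance_series(inside, list(field), 0:2), "frame 2")
})

test_that("first contact time scans series and respects the radius", {
  mk <- function(times, dists) data.frame(track_id = 1, frame = seq_along(times),
                                          time_s = times, distance_um = dists)
  s <- mk(c(0, 1, 2), c(0.05, 2, 3))
  expect_equal(first_contact_time(list(s), 0.1), 0)
  far <- mk(c(0, 1, 2), c(5, 4, 3))
  expect_true(is.na(first_contact_time(list(far), 0.1)))
  two <- list(mk(c(0, 2, 4), c(3, 0.4, 0.05)), mk(c(0, 2), c(0.3, 2)))
  expect_equal(first_contact_time(two, 0.1), 4)
  expect_equal(first_contact_time(two, 0.3), 0)
  # non-increasing in the radius
  radii <- c(0.05, 0.1, 0.3, 0.5, 1)
  fc <- vapply(radii, function(r) {
    v <- first_contact_time(two, r); if (is.na(v)) Inf else v
  }, numeric(1))
  expect_true(all(diff(fc) <= 0))
})

test_that("lag50 recovers the planted 50 s vesicle-arrival lag", {
  res <- cached_pipeline("lag50")
  expect_equal(res$appearance$cluster, 0)
  expect_equal(res$first_contact_time_s, 50)
  expect_equal(res$first_contact_time_s - res$appearance$cluster, 50)
})

test_that("appearance time requires persistence", {
  obj <- function(present, t) {
    m <- matrix(0, 30, 30); if (present) m[10:12, 10:12] <- 100
    segment_frame(m, 50, min_size = 1, frame_index = t, channel = 1L)
  }
  steady <- lapply(1:6, function(t) obj(TRUE, t))
  expect_equal(appearance_time(steady, frame_times = 0:5 * 1.5), 0)
  blip <- lapply(1:6, function(t) obj(t == 2, t))
  expect_true(is.na(appearance_time(blip, frame_times = 0:5 * 1.5,
                                    min_persistence = 3)))
  late <- lapply(1:8, function(t) obj(t >= 4, t))
  expect_equal(appearance_time(late, frame_times = (0:7) * 2,
                               min_persistence = 3), 6)
})

test_that("noise-free recruitment lag is recovered within one frame interval", {
  p <- generator_params(field_shape = c(64, 64), n_frames = 24,
                        frame_interval = 1.5, n_clusters = 2, n_vesicles = 2,
                        vesicle_recruitment_window = c(9, 14),
                        vesicle_speed = 0.15, noise_free = TRUE,
                        background = 0)
  sim <- simulate_timelapse(p, seed = 4)
  det <- detect_channel(sim$images, "vesicle", spot_sigma = 1.2)
  t_app <- appearance_time(det, frame_times(sim$images))
  t_true <- min(sim$truth$vesicles$recruitment_time_s)
  expect_gte(t_app, t_true - 1e-9)
  expect_lte(t_app, t_true + p$frame_interval)
})
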