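test_that("touch test honours overlap, separation and tolerance", {
  lab <- matrix(0L, 20, 20); lab[5:10, 5:10] <- 1L
  v_overlap <- matrix(FALSE, 20, 20); v_overlap[10:12, 10:12] <- TRUE
  expect_true(touch_test(v_overlap, lab, tolerance = 0)$contact)
  v_far <- matrix(FALSE, 20, 20); v_far[13:15, 5:7] <- TRUE # 3 px separation
  expect_false(touch_test(v_far, lab, tolerance = 1)$contact)
  v_adj <- matrix(FALSE, 20, 20); v_adj[11:13, 5:7] <- TRUE # 1 px separation
  # brute-force minimum pixel distance confirms the planted gap
  gap <- min(outer(which(v_adj), which(lab > 0), function(a, b) {
    ca <- arrayInd(a, c(20, 20)); cb <- arrayInd(b, c(20, 20))
    sqrt((ca[, 1] - cb[, 1])^2 + (ca[, 2] - cb[, 2])^2)
  }))
  expect_equal(gap, 1)
  expect_true(touch_test(v_adj, lab, tolerance = 1)$contact)
  expect_false(touch_test(v_adj, lab, tolerance = 0)$contact)
  expect_error(touch_test(matrix(FALSE, 5, 5), lab), "geometry")
})

test_that("touched cluster is the one with greatest overlap, ties to smaller label", {
  lab <- matrix(0L, 20, 20)
  lab[5:8, 5:8] <- 2L; lab[5:8, 12:15] <- 1L
  v <- matrix(FALSE, 20, 20); v[6:7, 7:9] <- TRUE # overlaps label 2 more
  expect_equal(touch_test(v, lab, 1)$cluster, 2L)
  v2 <- matrix(FALSE, 20, 20); v2[6, 8] <- TRUE; v2[6, 12] <- TRUE
  expect_equal(touch_test(v2, lab, 0)$cluster, 1L) # equal overlap -> smaller
})

test_that("lifetime colocalization reproduces the planted worked examples", {
  res145 <- cached_pipeline("track145")
  expect_length(res145$records, 1)
  expect_equal(res145$records[[1]]$lifetime_fraction, 0.75)
  res213 <- cached_pipeline("track213")
  expect_equal(res213$records[[1]]$lifetime_fraction, 0.95)
  # and the per-frame flags equal the planted truth frame by frame
  sim <- cached_sim("track145")
  rec <- res145$records[[1]]
  expect_identical(rec$contact,
                   sim$truth$vesicle_frames$contact[rec$frame])
})

test_that("a track never near clusters scores zero", {
  cl <- segment_frame({m <- matrix(0, 40, 40); m[5:8, 5:8] <- 100; m}, 50,
                      frame_index = 1, channel = 1L)
  ve <- segment_frame({m <- matrix(0, 40, 40); m[30:32, 30:32] <- 100; m},
                      50, min_size = 1, frame_index = 1, channel = 2L)
  tr <- link_tracks(list(ve), max_disp = 5, max_gap = 0)[[1]]
  rec <- lifetime_colocalization(tr, list(cl), list(ve), tolerance = 1)
  expect_equal(rec$lifetime_fraction, 0)
  expect_error(lifetime_colocalization(tr, list(), list(ve)), "frame 1")
})

test_that("increasing tolerance never decreases a lifetime fraction", {
  sim <- cached_sim("track145")
  det_cl <- detect_channel(sim$images, "cluster", spot_sigma = 2)
  det_ve <- detect_channel(sim$images, "vesicle", spot_sigma = 1.2)
  tr <- link_tracks(det_ve)[[1]]
  fr <- vapply(c(0, 1, 2, 4, 8), function(tol)
    lifetime_colocalization(tr, det_cl, det_ve, tolerance = tol)$lifetime_fraction,
    numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("population association computes qualifying percentages", {
  mk <- function(frac, life = 10) structure(
    list(track_id = 1L, lifetime = life, lifetime_fraction = frac),
    class = "interaction_record")
  recs <- c(lapply(rep(0.9, 16), mk), lapply(rep(0.2, 4), mk))
  expect_equal(population_association(recs), 80)
  expect_equal(population_association(lapply(rep(1, 5), mk)), 100)
  # short tracks are excluded from the denominator
  recs2 <- c(lapply(rep(0.9, 3), mk), list(mk(0, life = 2)))
  expect_equal(population_association(recs2), 100)
  expect_error(population_association(list(mk(0.9, life = 2))),
               "min_lifetime")
  expect_error(population_association(recs, lifetime_threshold = 0), "0, 1")
})

test_that("Pearson coefficient matches hand-computed cases", {
  a <- matrix(c(1, 2, 3, 4), 2)
  expect_equal(pearson_coefficient(a, a), 1)
  expect_equal(pearson_coefficient(a, -a + 10), -1)
  expect_equal(pearson_coefficient(a, 2 * a), 1)
  expect_error(pearson_coefficient(a, matrix(5, 2, 2)), "variance")
  expect_error(pearson_coefficient(a, matrix(1, 3, 3)), "geometry")
})

test_that("Costes randomization yields a centred null and calibrated p", {
  set.seed(99)
  noise_a <- matrix(rnorm(40 * 40), 40)
  noise_b <- matrix(rnorm(40 * 40), 40)
  res <- costes_randomization(noise_a, noise_b, block = 5,
                              iterations = 100, seed = 2)
  se <- stats::sd(res$null_r) / sqrt(res$iterations)
  expect_lt(abs(mean(res$null_r)), 3 * se + 0.02)
  expect_length(res$null_r, 100)
  # identical structured channels: observed r beats every scramble
  spots <- spot_frame(c(40, 40), rbind(c(10, 10), c(25, 30), c(32, 12)),
                      sigma = 2, amplitude = 100)
  res2 <- costes_randomization(spots, spots, block = 5, iterations = 99,
                               seed = 3)
  expect_equal(res2$observed_r, 1)
  expect_equal(res2$p_value, 1 / 100)
  # determinism and the minimum-tile contract
  res3 <- costes_randomization(spots, spots, block = 5, iterations = 99,
                               seed = 3)
  expect_identical(res2$null_r, res3$null_r)
  expect_error(costes_randomization(spots, spots, block = 40), "tiles")
})

test_that("Costes p values are uniform under the null", {
  set.seed(7)
  p <- vapply(1:40, function(i) {
    a <- matrix(rnorm(30 * 30), 30)
    b <- matrix(rnorm(30 * 30), 30)
    costes_randomization(a, b, block = 5, iterations = 39,
                         seed = 1000 + i)$p_value
  }, numeric(1))
  # binomial check at two quantiles (3 sigma)
  for (q in c(0.25, 0.5)) {
    expect_lt(abs(mean(p <= q) - q), 3 * sqrt(q * (1 - q) / 40) + 1 / 40)
  }
})

test_that("the spatiotemporal map classifies path segments by contact", {
  res <- cached_pipeline("track145")
  f <- tempfile(fileext = ".png")
  map <- spatiotemporal_map(res$records, res$tracks,
                            res$detections$cluster, file = f)
  expect_true(file.exists(f))
  expect_equal(sum(map$table$contact), 15)
  expect_equal(sum(!map$table$contact), 5)
  unlink(f)
})
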