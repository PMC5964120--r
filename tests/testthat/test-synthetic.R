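test_that("preset lookup validates names and encodes planted contracts", {
  expect_error(make_preset("nope"), "valid presets.*track145")
  p <- make_preset("lag50")
  expect_equal(p$frame_interval, 2)
  expect_equal(p$plant$expected$first_contact_frame, 26L) # 25 intervals in
  expect_equal(p$plant$expected$lag_s, 50)
  expect_equal(make_preset("track145")$plant$expected$lifetime_fraction, 0.75)
  expect_equal(make_preset("track213")$plant$expected$lifetime_fraction, 0.95)
  ps <- make_preset("paper_synapse")
  expect_equal(ps$plant$expected$n_high, 16L)
  expect_equal(ps$plant$expected$association_pct, 80)
  for (nm in c("two_phase_tirf", "two_phase_llsm")) {
    tp <- make_preset(nm)
    expect_equal(tp$vesicle_recruitment_window, c(45, 60))
    expect_equal(tp$frame_interval, 1.5)
    expect_gte((tp$n_frames - 1) * tp$frame_interval, 200)
  }
})

test_that("planted truth fractions match the preset contracts", {
  tr <- cached_sim("track145")$truth
  expect_equal(tr$vesicles$lifetime_fraction, 0.75)
  expect_equal(sum(tr$vesicle_frames$contact), 15)
  ps <- cached_sim("paper_synapse", seed = 1)$truth
  expect_equal(sum(ps$vesicles$lifetime_fraction >= 0.80), 16)
  expect_equal(sum(ps$vesicles$lifetime_fraction <= 0.30), 4)
})

test_that("identical parameters and seed give bit-identical output", {
  p <- generator_params(field_shape = c(48, 48), n_frames = 6,
                        n_clusters = 3, n_vesicles = 3,
                        vesicle_recruitment_window = c(0, 3),
                        flare_prob = 0.5, dwell_prob = 1, dwell_duration = 2)
  a <- simulate_timelapse(p, seed = 7)
  b <- simulate_timelapse(p, seed = 7)
  expect_identical(a$images$data, b$images$data)
  expect_identical(a$truth, b$truth)
  c <- simulate_timelapse(p, seed = 8)
  expect_false(identical(a$images$data, c$images$data))
})

test_that("noise-free static scene renders identical frames", {
  p <- generator_params(field_shape = c(32, 32), n_frames = 5,
                        n_clusters = 1, n_vesicles = 0,
                        noise_free = TRUE, background = 10)
  sim <- simulate_timelapse(p, seed = 1)
  f1 <- get_frame(sim$images, 1, "cluster")
  for (t in 2:5) expect_identical(get_frame(sim$images, t, "cluster"), f1)
  expect_equal(max(get_frame(sim$images, 1, "vesicle")), 10) # background only
})

test_that("no vesicle photons precede the earliest planted recruitment", {
  p <- generator_params(field_shape = c(48, 48), n_frames = 20,
                        frame_interval = 1.5, n_clusters = 2, n_vesicles = 3,
                        vesicle_recruitment_window = c(9, 15),
                        noise_free = TRUE, background = 5)
  sim <- simulate_timelapse(p, seed = 3)
  first_rec <- min(sim$truth$vesicles$recruitment_time_s)
  expect_gte(first_rec, 9)
  pre <- which(frame_times(sim$images) < first_rec)
  for (t in pre) {
    expect_equal(max(get_frame(sim$images, t, "vesicle")), 5)
  }
  post_max <- max(get_frame(sim$images, n_frames(sim$images), "vesicle"))
  expect_gt(post_max, 5)
})

test_that("flares multiply both channels locally for exactly their duration", {
  base <- function(amp) generator_params(
    field_shape = c(48, 48), n_frames = 12, n_clusters = 2, n_vesicles = 1,
    vesicle_recruitment_window = c(0, 0), vesicle_speed = 0.2,
    dwell_prob = 1, dwell_duration = 6, flare_prob = 1,
    flare_amplitude = amp, flare_duration = 3,
    noise_free = TRUE, background = 0)
  with_flare <- simulate_timelapse(base(2.5), seed = 5)
  without <- simulate_timelapse(base(1), seed = 5) # identical RNG draws
  fl <- with_flare$truth$flares
  expect_gt(nrow(fl), 0)
  expect_true(all(with_flare$truth$vesicles$associated[fl$vesicle]))
  flaring <- unique(unlist(lapply(seq_len(nrow(fl)), function(i)
    seq(fl$start_frame[i], length.out = fl$duration[i]))))
  vf <- with_flare$truth$vesicle_frames
  for (ch in c("cluster", "vesicle")) {
    for (t in seq_len(12)) {
      a <- get_frame(with_flare$images, t, ch)
      b <- get_frame(without$images, t, ch)
      if (t %in% flaring) {
        # at the vesicle position both channels scale by the amplitude
        pos <- round(c(vf$y_px[vf$frame == t], vf$x_px[vf$frame == t]))
        expect_equal(a[pos[1], pos[2]] / b[pos[1], pos[2]], 2.5,
                     tolerance = 1e-10)
      } else {
        expect_equal(a, b, tolerance = 1e-12)
      }
    }
  }
})

test_that("invalid geometry and parameters are rejected", {
  expect_error(generator_params(n_frames = 0), "n_frames")
  expect_error(generator_params(vesicle_recruitment_window = c(5, 2)),
               "lag_min")
  expect_error(generator_params(assoc_fraction = 1.2), "\\[0, 1\\]")
  tiny <- generator_params(field_shape = c(12, 12), n_clusters = 4,
                           n_vesicles = 0)
  expect_error(simulate_timelapse(tiny, seed = 1), "too small")
})
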