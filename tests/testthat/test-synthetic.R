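test_that("respiratory trajectory is periodic, deterministic, and dwells at end-expiration", {
  cfg <- sim_config(duration = 8, respiratory_period = 4, frame_rate = 15,
                    dwell_exponent = 4)
  tr <- respiratory_trajectory(cfg)
  expect_equal(nrow(tr), 8 * 15)
  # periodicity: one period is exactly 60 frames
  expect_equal(tr$y[1:60], tr$y[61:120], tolerance = 1e-12)
  expect_identical(tr, respiratory_trajectory(cfg))

  # dwell: mean per-frame displacement in the end-expiration decile is
  # smaller than in the mid-inspiration decile, for exponents > 1
  for (p in c(2, 4, 8)) {
    cfg_p <- sim_config(duration = 4, respiratory_period = 4,
                        dwell_exponent = p)
    tr_p <- respiratory_trajectory(cfg_p)
    disp <- sqrt(diff(tr_p$x)^2 + diff(tr_p$y)^2)
    phase <- (tr_p$t[-1] %% 4) / 4
    end_exp <- disp[phase <= 0.05 | phase >= 0.95]
    mid_insp <- disp[abs(phase - 0.25) <= 0.05]
    expect_lt(mean(end_exp), mean(mid_insp))
  }
})

test_that("higher dwell exponent concentrates frames at the end-expiration extremum", {
  count_near_extremum <- function(p) {
    cfg <- sim_config(duration = 4, respiratory_period = 4,
                      dwell_exponent = p, motion_amplitude = 18)
    tr <- respiratory_trajectory(cfg)
    d <- sqrt((tr$x - cfg$stone_start[1])^2 + (tr$y - cfg$stone_start[2])^2)
    sum(d <= 1)
  }
  expect_gt(count_near_extremum(4), count_near_extremum(1))
})

test_that("trajectory configuration errors are caught", {
  expect_error(sim_config(respiratory_period = 0), "period")
  expect_error(sim_config(motion_amplitude = -1), "amplitude")
  expect_error(sim_config(dwell_exponent = 0.5), "dwell_exponent")
  expect_error(sim_config(motion_amplitude = 500), "leaves the image")
})

test_that("rendered frames carry exact ground truth", {
  cfg <- sim_config(duration = 1)
  tr <- respiratory_trajectory(cfg)
  # frame 0: stone at end-expiration = focal-zone centre, fully inside
  f0 <- render_frame(tr, 0L, cfg)
  expect_equal(f0$true_overlap, 1.0)
  expect_identical(f0$true_label, "in_focus")
  expect_true(all(dim(f0$image) == c(64, 64)))

  # stone far from a small displaced zone: zero overlap
  cfg2 <- cfg
  cfg2$focal_zone <- focal_zone(c(10, 50), c(4, 4))
  f <- render_frame(tr, 0L, cfg2)
  expect_equal(f$true_overlap, 0.0)
  expect_identical(f$true_label, "out_of_focus")

  # rectangle zone whose edge passes through the stone centre: the stone
  # straddles the boundary symmetrically, overlap 0.5 up to rasterization
  cfg3 <- cfg
  cfg3$focal_zone <- focal_zone(c(32 - 10, 22), c(10, 20), shape = "rectangle")
  f3 <- render_frame(tr, 0L, cfg3)
  # independent pixel-count oracle over the stone mask
  xs <- matrix(rep(0:63, each = 64), 64, 64)
  ov_expect <- sum(f3$stone_mask[xs <= 32]) / sum(f3$stone_mask)
  expect_equal(f3$true_overlap, ov_expect)
  npix <- sum(f3$stone_mask)
  expect_lte(abs(f3$true_overlap - 0.5), (2 * cfg$stone_axes[2] + 1) / npix)
  if (f3$true_overlap >= 0.5) expect_identical(f3$true_label, "in_focus")
})

test_that("stone mask area matches the ellipse area within rasterization tolerance", {
  cfg <- sim_config(duration = 2)
  s <- generate_sequence(cfg)
  area <- pi * prod(cfg$stone_axes)
  for (f in s$frames[c(1, 10, 20, 30)]) {
    expect_gt(sum(f$stone_mask), 0)
    expect_lt(abs(sum(f$stone_mask) - area) / area, 0.15)
  }
})

test_that("generated sequences are reproducible and internally consistent", {
  cfg <- small_sim_config(duration = 4, frame_rate = 15)
  s1 <- generate_sequence(cfg)
  expect_length(s1$frames, 60)
  expect_identical(s1, generate_sequence(cfg))  # bit-identical under one seed

  for (f in s1$frames) {
    # exact label consistency with the overlap rule
    expect_identical(f$true_label == "in_focus", f$true_overlap >= 0.5)
    # generator labels agree with classify_frame on ground-truth masks
    cl <- classify_frame(f$stone_mask, cfg$focal_zone)
    expect_identical(cl$value, f$true_label)
  }
  expect_identical(s1$labels,
                   vapply(s1$frames, function(f)
                     as.integer(f$true_label == "in_focus"), integer(1)))
})

test_that("a 60 s sequence at 15 frames/s yields 900 frames", {
  cfg <- sim_config(duration = 60)
  tr <- respiratory_trajectory(cfg)
  expect_equal(nrow(tr), 900)
})

test_that("cohort simulation controls hit-rate heterogeneity", {
  expect_error(simulate_cohort(2), ">= 3")

  # no jitter: every patient shares one hit rate, chi-square is ~0
  co0 <- simulate_cohort(4, small_sim_config(duration = 4), jitter = 0,
                         seed = 11)
  pf0 <- cohort_patient_frames(co0)
  expect_equal(length(unique(pf0$rate)), 1L)
  expect_lt(pooling_chi2(pf0)$chi2, 1e-8)

  # strong jitter: rates spread over ~20-90% and pooling is rejected
  co1 <- simulate_cohort(11, small_sim_config(duration = 6), jitter = 1,
                         seed = 11)
  pf1 <- cohort_patient_frames(co1)
  expect_gt(diff(range(pf1$rate)), 0.4)
  pc <- pooling_chi2(pf1)
  expect_lt(pc$p_value, 0.05)
  expect_false(pc$pooled)
})
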