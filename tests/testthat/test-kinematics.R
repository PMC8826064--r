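cfg <- run_config()

test_that("bin boundary positions are linear interpolations of the fixes", {
  fixes <- data.frame(t_s = c(0, 1200), x_km = c(0, 0), y_km = c(0, -2))
  bins <- make_bins(0, 1200, 600)
  bp <- interpolate_bin_positions(fixes, bins)
  expect_equal(c(bp$x0[2], bp$y0[2]), c(0, -1))        # midpoint in time
  expect_equal(c(bp$x0[1], bp$y0[1]), c(0, 0))         # coincides with a fix
  expect_false(any(bp$missing))

  # boundary outside the fix record: bin flagged missing
  late_fixes <- data.frame(t_s = c(300, 1200), x_km = c(0, 0), y_km = c(0, -2))
  bp2 <- interpolate_bin_positions(late_fixes, bins)
  expect_true(bp2$missing[1])
  expect_false(bp2$missing[2])

  expect_error(interpolate_bin_positions(fixes[1, ], bins), "at least 2")
})

test_that("speed, southerly speed, course, and deviation follow the bearing math", {
  bins <- data.frame(bin_index = 0:1, t_start_s = c(0, 600),
                     t_end_s = c(600, 1200), missing = FALSE,
                     x0 = c(0, 0), y0 = c(0, -0.683),
                     x1 = c(0, 0), y1 = c(-0.683, -1.366))
  k <- compute_bin_kinematics(bins)
  expect_equal(k$speed_kmh, c(4.098, 4.098), tolerance = 1e-9)
  expect_equal(k$speed_south_kmh, c(4.098, 4.098), tolerance = 1e-9)
  expect_equal(k$course_deg, c(180, 180))
  expect_true(is.na(k$course_dev_deg[1]))  # no previous bin
  expect_equal(k$course_dev_deg[2], 0)

  # due-east movement has zero southerly speed
  east <- data.frame(bin_index = 0, t_start_s = 0, t_end_s = 600,
                     missing = FALSE, x0 = 0, y0 = 0, x1 = 1, y1 = 0)
  ke <- compute_bin_kinematics(east)
  expect_equal(ke$speed_south_kmh, 0)
  expect_equal(ke$course_deg, 90)

  # circular wrap: 350 -> 10 degrees is a 20-degree deviation
  wrap <- data.frame(bin_index = 0:1, t_start_s = c(0, 600),
                     t_end_s = c(600, 1200), missing = FALSE,
                     x0 = c(0, 0), y0 = c(0, 1),
                     x1 = sin(c(350, 10) * pi / 180) + c(0, 0),
                     y1 = cos(c(350, 10) * pi / 180) + c(0, 1))
  kw <- compute_bin_kinematics(wrap)
  expect_equal(kw$course_deg, c(350, 10), tolerance = 1e-9)
  expect_equal(kw$course_dev_deg[2], 20, tolerance = 1e-9)

  # zero displacement carries the previous course with deviation 0
  still <- data.frame(bin_index = 0:1, t_start_s = c(0, 600),
                      t_end_s = c(600, 1200), missing = FALSE,
                      x0 = c(0, 1), y0 = c(0, 0), x1 = c(1, 1), y1 = c(0, 0))
  ks <- compute_bin_kinematics(still)
  expect_equal(ks$speed_kmh[2], 0)
  expect_equal(ks$course_deg[2], 90)
  expect_equal(ks$course_dev_deg[2], 0)
})

test_that("dive segmentation applies the strict depth and duration thresholds", {
  flat <- data.frame(t_s = 0:500, depth_m = rep(2, 501))
  seg <- segment_dives(flat, cfg)
  expect_equal(nrow(seg$dives), 0)
  expect_equal(seg$surface, data.frame(t_start_s = 0, t_end_s = 500))

  # 12 m for ~80 s qualifies on both rules
  z <- c(rep(1, 50), rep(12, 80), rep(1, 50))
  one <- data.frame(t_s = seq_along(z) - 1, depth_m = z)
  seg1 <- segment_dives(one, cfg)
  expect_equal(nrow(seg1$dives), 1)
  expect_equal(seg1$dives$max_depth_m, 12)
  expect_gt(seg1$dives$duration_s, 75)

  # too short (70 s) and too shallow (9 m) excursions are rejected
  z2 <- c(rep(1, 20), rep(12, 70), rep(1, 20), rep(9, 300), rep(1, 20))
  seg2 <- segment_dives(data.frame(t_s = seq_along(z2) - 1, depth_m = z2), cfg)
  expect_equal(nrow(seg2$dives), 0)

  expect_equal(nrow(segment_dives(flat[0, ], cfg)$dives), 0)
})

test_that("segmentation matches the brute-force oracle and tiles the record", {
  set.seed(101)
  for (rep in 1:200) {
    prof <- random_depth_profile(n = sample(80:200, 1),
                                 dt = sample(c(1, 2, 5), 1))
    seg <- segment_dives(prof, cfg)
    ora <- oracle_segment_dives(prof, cfg$deep_dive_depth_m,
                                cfg$deep_dive_duration_s)
    expect_equal(nrow(seg$dives), nrow(ora))
    if (nrow(ora)) {
      expect_equal(seg$dives$t_start_s, ora$t_start_s, tolerance = 1e-9)
      expect_equal(seg$dives$t_end_s, ora$t_end_s, tolerance = 1e-9)
      expect_equal(seg$dives$max_depth_m, ora$max_depth_m)
      expect_true(all(seg$dives$mean_depth_m <= seg$dives$max_depth_m))
    }
    # dives and surface intervals tile the record exactly
    total <- sum(seg$dives$t_end_s - seg$dives$t_start_s) +
      sum(seg$surface$t_end_s - seg$surface$t_start_s)
    expect_equal(total, max(prof$t_s) - min(prof$t_s), tolerance = 1e-6)
  }
})

test_that("bin dive metrics prorate boundary-spanning dives", {
  # one dive from t = 590 to 790: initiated in bin 0, time split across bins
  z <- rep(1, 1201)
  z[592:790] <- 20
  depth <- data.frame(t_s = 0:1200, depth_m = z)
  seg <- segment_dives(depth, cfg)
  expect_equal(nrow(seg$dives), 1)
  bins <- make_bins(0, 1200, 600)
  bm <- compute_bin_dive_metrics(seg, bins)
  expect_equal(bm$dive_count, c(1L, 0L))
  d0 <- seg$dives$t_start_s
  d1 <- seg$dives$t_end_s
  expect_equal(bm$surface_prop, c((600 - (600 - d0)) / 600,
                                  (600 - (d1 - 600)) / 600), tolerance = 1e-9)

  none <- segment_dives(data.frame(t_s = 0:1200, depth_m = rep(1, 1201)), cfg)
  bm0 <- compute_bin_dive_metrics(none, bins)
  expect_equal(bm0$surface_prop, c(1, 1))
  expect_equal(bm0$dive_count, c(0L, 0L))
})

test_that("the metric table has one row per complete bin with exclusions flagged", {
  sim <- simulate_pair_dataset(sim_config(n_tags = 4, bins_range = c(3, 8)),
                               seed = 11)
  metrics <- build_metric_table(sim$datasets)
  expect_equal(nrow(metrics), nrow(sim$truth$bins))
  # the first bin of each tag lacks course deviation and is excluded
  first <- metrics[metrics$bin_index == 0, ]
  expect_true(all(first$excluded))
  rest <- metrics[metrics$bin_index > 0, ]
  expect_false(any(rest$excluded))
  expect_true(all(rest$course_dev_deg >= 0 & rest$course_dev_deg <= 180))
  expect_true(all(abs(rest$speed_south_kmh) <= rest$speed_kmh + 1e-9))
  expect_true(all(rest$surface_prop >= 0 & rest$surface_prop <= 1))
})
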