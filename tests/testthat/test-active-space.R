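cfg <- run_config()

test_that("broadband level is the power sum of in-band third-octave levels", {
  expect_equal(broadband_noise_level(c(`100` = 90, `200` = 90)),
               90 + 10 * log10(2), tolerance = 1e-9)
  expect_equal(broadband_noise_level(c(`500` = 97.3)), 97.3)
  for (n in c(2, 5, 10)) {
    bands <- setNames(rep(88, n), seq(50, by = 100, length.out = n))
    expect_equal(broadband_noise_level(bands), 88 + 10 * log10(n),
                 tolerance = 1e-9)
  }
  # bands outside 40-2500 Hz are ignored
  expect_equal(broadband_noise_level(c(`20` = 120, `500` = 90, `5000` = 120)),
               90)
  expect_error(broadband_noise_level(c(`20` = 120)), "no bands")
})

test_that("calls are matched to the most recent noise sample within the window", {
  noise <- data.frame(t_s = c(0, 600, 1200), broadband_db = c(95, 98, 101))
  m <- match_noise_to_call(c(630, 600, 1900, 50), noise, window = 600)
  expect_equal(m$noise_db, c(98, 98, NA, 95))   # 30 s after; exactly at; stale; 50 s after
  expect_equal(m$excluded, c(FALSE, FALSE, TRUE, FALSE))
  # sample 700 s before the call with a 600-s window is too old
  m2 <- match_noise_to_call(700, data.frame(t_s = 0, broadband_db = 95), 600)
  expect_true(m2$excluded)
})

test_that("the octave band containing the peak frequency is selected", {
  tl <- load_tl_bands()
  expect_equal(tl$center_hz[select_tl_band(500, tl)], 500)
  expect_equal(tl$center_hz[select_tl_band(125, tl)], 125)
  # octave edges: [fc/sqrt(2), fc*sqrt(2))
  expect_equal(tl$center_hz[select_tl_band(500 * sqrt(2) - 1e-9, tl)], 500)
  expect_equal(tl$center_hz[select_tl_band(500 * sqrt(2) + 1e-9, tl)], 1000)
  expect_error(select_tl_band(10, tl), "outside")
})

test_that("piecewise TL evaluates both slopes and is continuous at the crossover", {
  band <- list(a_db = 20, b_near = 15, b_far = 20, crossover_m = 200)
  expect_equal(transmission_loss(band, 1), 20)             # log10(1) = 0
  b2 <- list(a_db = 20, b_near = 15, b_far = 20, crossover_m = 1000)
  expect_equal(transmission_loss(b2, 100), 50)             # 20 + 15*2
  expect_equal(transmission_loss(band, 2000),
               20 + 15 * log10(200) + 20 * 1, tolerance = 1e-9)
  # continuity from both sides of the crossover
  eps <- 1e-9
  expect_equal(transmission_loss(band, 200 - eps),
               transmission_loss(band, 200 + eps), tolerance = 1e-6)
  # single-slope band: crossover = Inf
  b3 <- list(a_db = 5, b_near = 18, b_far = 99, crossover_m = Inf)
  expect_equal(transmission_loss(b3, 1e4), 5 + 18 * 4)
  # clamped below the 1-m reference
  expect_equal(transmission_loss(band, 0.1), 20)
})

test_that("detection distance inverts the TL model, with flooring when SNR <= 0", {
  band <- data.frame(a_db = 20, b_near = 15, b_far = 20, crossover_m = 500)
  est <- detection_distance(148, 98, band, cfg)
  expect_equal(est$distance_m, 100, tolerance = 1e-9)
  expect_false(est$floored)
  expect_equal(148 - transmission_loss(band, est$distance_m) - 98, 0,
               tolerance = 1e-9)

  # no positive-SNR range: floored at 1 m
  est0 <- detection_distance(120, 120, band, cfg)
  expect_true(est0$floored)
  expect_equal(est0$distance_m, 1)

  # far-piece solution, verified by forward evaluation
  band2 <- data.frame(a_db = 20, b_near = 15, b_far = 20, crossover_m = 200)
  est2 <- detection_distance(168, 98, band2, cfg)
  expect_gt(est2$distance_m, 200)
  expect_equal(est2$distance_m, 200 * 10^((50 - 15 * log10(200)) / 20),
               tolerance = 1e-9)
  expect_equal(168 - transmission_loss(band2, est2$distance_m) - 98, 0,
               tolerance = 1e-6)
})

test_that("detection distance is monotone in received level and noise", {
  band <- data.frame(a_db = 10, b_near = 16, b_far = 22, crossover_m = 400)
  rl <- seq(125, 170, by = 5)
  d_rl <- detection_distance(rl, 98, band, cfg)$distance_m
  expect_true(all(diff(d_rl) > 0))
  nz <- seq(94, 104, by = 1)
  d_nz <- detection_distance(150, nz, band, cfg)$distance_m
  expect_true(all(diff(d_nz) < 0))
})

test_that("the gamma state model recovers a planted multiplicative effect", {
  set.seed(81)
  n <- 300
  tag <- sprintf("t%02d", sample(1:15, n, replace = TRUE))
  tag_eff <- setNames(rnorm(15, 0, 0.2), sprintf("t%02d", 1:15))
  state <- sample(c("resting_milling", "travelling"), n, replace = TRUE)
  mu <- 500 * exp(tag_eff[tag]) * ifelse(state == "travelling", 1.5, 1)
  d <- data.frame(tag_id = tag, state = state,
                  distance_m = rgamma(n, shape = 4, rate = 4 / mu),
                  floored = FALSE)
  m <- fit_detection_distance_model(d)
  expect_lt(abs(m$contrast$log_estimate - log(1.5)),
            2 * m$contrast$se)

  # degenerate input: flagged, no crash
  d$distance_m <- 500
  expect_warning(m0 <- fit_detection_distance_model(d), "degenerate")
  expect_true(m0$degenerate)
})

test_that("the RL x noise surface summarises medians per cell", {
  one <- data.frame(received_level_db = 148.3, noise_db = 97.2,
                    distance_m = 432)
  s1 <- distance_surface_summary(one)
  expect_equal(nrow(s1), 1)
  expect_equal(s1$median_distance_m, 432)
  expect_equal(s1$n, 1)
  # refining the grid leaves a singleton's value unchanged
  s2 <- distance_surface_summary(one, rl_step = 0.5, noise_step = 0.25)
  expect_equal(s2$median_distance_m, 432)

  # monotone data give monotone cell medians along RL at fixed noise
  band <- data.frame(a_db = 10, b_near = 16, b_far = 22, crossover_m = 400)
  rl <- rep(seq(126, 170, by = 2), each = 3)
  est <- data.frame(received_level_db = rl, noise_db = 98,
                    distance_m = detection_distance(rl, 98, band,
                                                    cfg)$distance_m)
  s3 <- distance_surface_summary(est, rl_step = 2, noise_step = 1)
  expect_true(all(diff(s3$median_distance_m) > 0))
})
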