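# Independent brute-force dive segmenter: walks the samples one by one,
# tracks whether the trace is below the threshold, and interpolates each
# threshold crossing as it happens. Deliberately naive; used as the oracle
# against the vectorized segmenter.
oracle_segment_dives <- function(depth, thr = 10, min_dur = 75) {
  t <- depth$t_s; z <- depth$depth_m
  n <- length(t)
  dives <- list()
  below <- FALSE
  t0 <- NA_real_
  idx0 <- NA_integer_
  for (i in seq_len(n)) {
    if (!below && z[i] > thr) {
      below <- TRUE
      idx0 <- i
      t0 <- if (i == 1) t[1] else {
        t[i - 1] + (thr - z[i - 1]) / (z[i] - z[i - 1]) * (t[i] - t[i - 1])
      }
    } else if (below && z[i] <= thr) {
      t1 <- t[i - 1] + (thr - z[i - 1]) / (z[i] - z[i - 1]) * (t[i] - t[i - 1])
      dives[[length(dives) + 1]] <-
        c(t0 = t0, t1 = t1, maxd = max(z[idx0:(i - 1)]))
      below <- FALSE
    }
  }
  if (below) {
    dives[[length(dives) + 1]] <- c(t0 = t0, t1 = t[n], maxd = max(z[idx0:n]))
  }
  if (!length(dives)) {
    return(data.frame(t_start_s = numeric(), t_end_s = numeric(),
                      max_depth_m = numeric()))
  }
  m <- do.call(rbind, dives)
  out <- data.frame(t_start_s = m[, "t0"], t_end_s = m[, "t1"],
                    max_depth_m = m[, "maxd"])
  out[out$t_end_s - out$t_start_s > min_dur & out$max_depth_m > thr, ,
      drop = FALSE]
}

# random depth profile: a reflected random walk with occasional plunges so
# threshold crossings of every geometry occur
random_depth_profile <- function(n = 150, dt = 1) {
  z <- numeric(n)
  z[1] <- runif(1, 0, 15)
  for (i in 2:n) {
    step <- rnorm(1, 0, 3) + if (runif(1) < 0.05) sample(c(-12, 12), 1) else 0
    z[i] <- abs(z[i - 1] + step)
  }
  data.frame(t_s = seq(0, by = dt, length.out = n), depth_m = z)
}

# small planted two-state metric table mirroring the published cluster
# means, for clustering tests that do not need the full generator
planted_metric_table <- function(n_per_state = 60) {
  mk <- function(n, state, speed, ssouth, cdev, esb, surf, dive) {
    data.frame(
      tag_id = rep(sprintf("t%02d", 1:6), length.out = n),
      bin_index = seq_len(n),
      t_start_s = seq_len(n) * 600,
      speed_kmh = pmax(0.05, rnorm(n, speed, 0.7)),
      speed_south_kmh = rnorm(n, ssouth, 0.7),
      course_deg = runif(n, 0, 360),
      course_dev_deg = pmin(180, pmax(0, rnorm(n, cdev, 20))),
      esb_count = rpois(n, esb),
      surface_prop = pmin(1, pmax(0, rnorm(n, surf, 0.08))),
      dive_count = rpois(n, dive),
      excluded = FALSE,
      true_state = state)
  }
  out <- rbind(
    mk(n_per_state, "resting_milling", 1.7, 0.3, 91, 0.30, 0.34, 0.83),
    mk(n_per_state, "travelling", 4.6, 4.1, 21, 0.21, 0.20, 1.79))
  out$bin_index <- seq_len(nrow(out))  # unique keys
  out
}
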