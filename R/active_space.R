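#' Broadband level from third-octave band levels
#'
#' Power sum of the third-octave band levels within the analysis band
#' (default 40 Hz to 2.5 kHz, where nearly all female-calf call energy and
#' the peak of wind-dominated noise lie): 10 log10(sum 10^(L_i/10)).
#'
#' @param band_levels Named numeric vector, names = band center frequencies
#'   (Hz), values = dB re 1 uPa.
#' @param band_low_hz,band_high_hz Band centers outside this range are
#'   ignored.
#' @return Broadband level, dB re 1 uPa.
#' @export
broadband_noise_level <- function(band_levels, band_low_hz = 40,
                                  band_high_hz = 2500) {
  fc <- as.numeric(names(band_levels))
  if (length(band_levels) && is.null(names(band_levels))) {
    fc <- rep(band_low_hz, length(band_levels))  # unnamed: assume in-band
  }
  keep <- fc >= band_low_hz & fc <= band_high_hz
  L <- band_levels[keep]
  if (!length(L)) stop("broadband_noise_level: no bands within ",
                       band_low_hz, "-", band_high_hz, " Hz")
  10 * log10(sum(10^(L / 10)))
}

#' Match each call to its most recent ambient-noise sample
#'
#' Ambient noise is sampled for 10 s every 10 min; a call is paired with the
#' most recent sample at or before it, provided that sample is no older than
#' `window` seconds. Calls with no sufficiently recent sample are excluded
#' from the active-space analysis (the exclusion is recorded, not an error).
#'
#' @param call_t Numeric vector of call times, s.
#' @param noise Data frame with `t_s` and `broadband_db`, sorted by time.
#' @param window Maximum sample age, s (default one sampling interval).
#' @return Data frame: `noise_db` (NA when excluded) and `excluded`.
#' @export
match_noise_to_call <- function(call_t, noise, window = 600) {
  idx <- findInterval(call_t, noise$t_s)   # last sample at or before the call
  noise_db <- rep(NA_real_, length(call_t))
  ok <- idx >= 1
  ok[ok] <- call_t[ok] - noise$t_s[idx[ok]] <= window
  noise_db[ok] <- noise$broadband_db[idx[ok]]
  data.frame(noise_db = noise_db, excluded = !ok)
}

#' Select the octave band containing a call's peak frequency
#'
#' Transmission loss was measured in octave bands; each call uses the band
#' whose octave interval [fc/sqrt(2), fc*sqrt(2)) contains its peak
#' frequency.
#'
#' @param peak_hz Numeric vector of call peak frequencies, Hz.
#' @param tl_bands A [load_tl_bands()] table.
#' @return Integer vector of row indices into `tl_bands`.
#' @export
select_tl_band <- function(peak_hz, tl_bands) {
  lo <- tl_bands$center_hz / sqrt(2)
  hi <- tl_bands$center_hz * sqrt(2)
  idx <- vapply(peak_hz, function(f) {
    hit <- which(f >= lo & f < hi)
    if (!length(hit)) {
      stop(sprintf(paste0("select_tl_band: peak frequency %g Hz outside the ",
                          "covered bands (%g-%g Hz)"), f, min(lo), max(hi)))
    }
    hit[1]
  }, integer(1))
  idx
}

#' Piecewise log-distance transmission loss
#'
#' TL(x) = a + b_near * log10(x) out to the crossover distance, continuing
#' with slope b_far beyond it; the two pieces join continuously at the
#' crossover. `a` is the (frequency-dependent) loss at the 1-m reference
#' distance. Distances below 1 m are clamped to 1 m.
#'
#' @param band One row of a [load_tl_bands()] table (or a list with `a_db`,
#'   `b_near`, `b_far`, `crossover_m`).
#' @param distance_m Numeric vector of distances, m.
#' @return Transmission loss, dB.
#' @export
transmission_loss <- function(band, distance_m) {
  x <- pmax(distance_m, 1)
  near <- band$a_db + band$b_near * log10(x)
  if (!is.finite(band$crossover_m)) return(near)
  tl_cross <- band$a_db + band$b_near * log10(band$crossover_m)
  ifelse(x <= band$crossover_m, near,
         tl_cross + band$b_far * log10(x / band$crossover_m))
}

#' Detection distance of a call: the range at which SNR reaches the threshold
#'
#' Inverts the piecewise transmission-loss model in closed form: the call is
#' audible out to the distance d where RL - TL(d) = noise + threshold
#' (threshold 0 dB by default, the assumed just-audible SNR). If the excess
#' level RL - N - threshold does not exceed TL at the distance floor, the
#' estimate is floored (default 1 m, the TL reference distance) and flagged.
#'
#' @param rl Received level(s), dB re 1 uPa (proxy for source level).
#' @param noise_db Matched broadband noise level(s), dB re 1 uPa.
#' @param band One row of the TL table (recycled) or rows matched per call.
#' @param config A [run_config()] (threshold and distance floor).
#' @return Data frame: `snr_at_tag`, `distance_m`, `floored`.
#' @export
detection_distance <- function(rl, noise_db, band, config = run_config()) {
  excess <- rl - noise_db - config$snr_threshold_db
  a <- band$a_db; bn <- band$b_near; bf <- band$b_far; xc <- band$crossover_m
  d_near <- 10^((excess - a) / bn)
  tl_cross <- a + bn * log10(xc)
  d_far <- xc * 10^((excess - tl_cross) / bf)
  d <- ifelse(is.finite(xc) & d_near > xc, d_far, d_near)
  # TL is strictly increasing, so the solution is at or below the floor
  # exactly when the excess level cannot exceed TL(floor)
  floored <- d <= config$distance_floor_m
  d <- pmax(d, config$distance_floor_m)
  data.frame(snr_at_tag = rl - noise_db, distance_m = d, floored = floored)
}

#' Detection-distance estimates for every usable call in a dataset
#'
#' Chains noise matching, band selection, and the closed-form inversion for
#' each call; calls without a recent noise sample are excluded (flagged, not
#' dropped silently). `near_surface` marks calls produced within 10 m of the
#' surface, whose detection distance is likely overestimated by a
#' depth-independent TL model (surface-reflection interference).
#'
#' @param calls Data frame with `t_s`, `received_level_db`,
#'   `peak_frequency_hz`, optionally `caller_depth_m`.
#' @param noise Data frame with `t_s`, `broadband_db`.
#' @param tl_bands A [load_tl_bands()] table.
#' @param config A [run_config()].
#' @return `calls` with `noise_db`, `noise_excluded`, `band_hz`,
#'   `snr_at_tag`, `distance_m`, `floored`, `near_surface` appended.
#' @export
estimate_detection_distances <- function(calls, noise, tl_bands,
                                         config = run_config()) {
  m <- match_noise_to_call(calls$t_s, noise, config$noise_window_s)
  calls$noise_db <- m$noise_db
  calls$noise_excluded <- m$excluded
  bidx <- select_tl_band(calls$peak_frequency_hz, tl_bands)
  calls$band_hz <- tl_bands$center_hz[bidx]
  calls$snr_at_tag <- NA_real_
  calls$distance_m <- NA_real_
  calls$floored <- NA
  ok <- !calls$noise_excluded
  if (any(ok)) {
    est <- detection_distance(calls$received_level_db[ok], calls$noise_db[ok],
                              tl_bands[bidx[ok], ], config)
    calls$snr_at_tag[ok] <- est$snr_at_tag
    calls$distance_m[ok] <- est$distance_m
    calls$floored[ok] <- est$floored
  }
  depth <- if (is.null(calls$caller_depth_m)) NA_real_ else calls$caller_depth_m
  calls$near_surface <- !is.na(depth) & depth < 10
  calls
}

#' Gamma mixed model of detection distance by behavioral state
#'
#' Detection distances are strictly positive and right-skewed, so they are
#' modeled with a gamma distribution and log link, random intercept per tag.
#' State least-squares means are back-transformed to metres and the
#' travelling - resting contrast reported on the log scale.
#'
#' @param estimates Data frame with `tag_id`, `distance_m`, `state`,
#'   `floored`.
#' @param include_floored Keep floored estimates (default FALSE: a floored
#'   distance is a censoring artifact, not a measurement).
#' @return List of class `distance_model`: `model`, `means` (m), `contrast`.
#' @export
fit_detection_distance_model <- function(estimates, include_floored = FALSE) {
  est <- estimates[!is.na(estimates$distance_m) & !is.na(estimates$state), ,
                   drop = FALSE]
  if (!include_floored) est <- est[!est$floored, , drop = FALSE]
  if (length(unique(est$tag_id)) < 2) {
    stop("fit_detection_distance_model: need >= 2 tags")
  }
  est$state <- factor(est$state, levels = c("resting_milling", "travelling"))
  small <- table(est$state) < 2
  if (any(small)) {
    warning("fit_detection_distance_model: a state has < 2 estimates; ",
            "contrast unreliable")
  }
  if (stats::sd(est$distance_m) == 0) {
    warning("fit_detection_distance_model: degenerate dispersion ",
            "(all distances equal); returning observed means without a fit")
    means <- data.frame(state = levels(est$state),
                        distance_m = rep(est$distance_m[1], 2))
    return(structure(list(model = NULL, means = means, contrast = NULL,
                          degenerate = TRUE), class = "distance_model"))
  }
  model <- glmmTMB::glmmTMB(distance_m ~ state + (1 | tag_id),
                            family = Gamma(link = "log"), data = est)
  emm <- emmeans::emmeans(model, ~state, type = "response")
  means <- as.data.frame(emm)
  names(means)[names(means) == "response"] <- "distance_m"
  con <- state_contrast(emm)
  structure(list(model = model, means = means, contrast = con),
            class = "distance_model")
}

#' Median detection distance over a received-level x noise grid
#'
#' A descriptive surface for plotting the joint effect of call level and
#' ambient noise on detection distance: bins (RL, noise) on a regular grid
#' and reports the median distance per occupied cell.
#'
#' @param estimates Output of [estimate_detection_distances()].
#' @param rl_step,noise_step Cell sizes, dB.
#' @return Data frame: `rl_mid`, `noise_mid`, `n`, `median_distance_m`.
#' @export
distance_surface_summary <- function(estimates, rl_step = 2, noise_step = 1) {
  est <- estimates[!is.na(estimates$distance_m), , drop = FALSE]
  if (!nrow(est)) stop("distance_surface_summary: no estimates")
  rl_cell <- floor(est$received_level_db / rl_step)
  nz_cell <- floor(est$noise_db / noise_step)
  key <- paste(rl_cell, nz_cell)
  agg <- lapply(split(seq_len(nrow(est)), key), function(i) {
    data.frame(rl_mid = (rl_cell[i[1]] + 0.5) * rl_step,
               noise_mid = (nz_cell[i[1]] + 0.5) * noise_step,
               n = length(i),
               median_distance_m = stats::median(est$distance_m[i]))
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$rl_mid, out$noise_mid), ]
  rownames(out) <- NULL
  out
}
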