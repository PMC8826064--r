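#' Run configuration for the pair-space pipeline
#'
#' Bundles the thresholds and conventions used throughout the analysis:
#' the 10-min binning of follows, the deep-dive definition (deeper than
#' 10 m for longer than 75 s), the audibility threshold (SNR = 0 dB), the
#' broadband noise band (40 Hz to 2.5 kHz), and the noise-matching window.
#'
#' @param bin_length_s Bin length in seconds. Default 600 (10 min).
#' @param deep_dive_depth_m Depth a dive must strictly exceed, in metres.
#' @param deep_dive_duration_s Duration a dive must strictly exceed, in seconds.
#' @param snr_threshold_db SNR (dB) at which a call is deemed just audible.
#' @param band_low_hz,band_high_hz Third-octave band range (Hz) integrated
#'   into the broadband noise level.
#' @param noise_window_s Maximum age (s) of a noise sample matched to a call;
#'   defaults to the noise sampling cadence (one sample per 10 min).
#' @param distance_floor_m Minimum reported detection distance (m); also the
#'   transmission-loss reference distance.
#' @param seed Integer seed recorded with results.
#'
#' @return An object of class `pairspace_config` (a named list).
#' @export
run_config <- function(bin_length_s = 600,
                       deep_dive_depth_m = 10,
                       deep_dive_duration_s = 75,
                       snr_threshold_db = 0,
                       band_low_hz = 40,
                       band_high_hz = 2500,
                       noise_window_s = 600,
                       distance_floor_m = 1,
                       seed = 1L) {
  stopifnot(bin_length_s > 0, bin_length_s %% 1 == 0,
            deep_dive_depth_m > 0, deep_dive_duration_s > 0,
            band_low_hz > 0, band_high_hz > band_low_hz,
            noise_window_s > 0, distance_floor_m > 0)
  structure(list(
    bin_length_s = as.numeric(bin_length_s),
    deep_dive_depth_m = deep_dive_depth_m,
    deep_dive_duration_s = deep_dive_duration_s,
    snr_threshold_db = snr_threshold_db,
    band_low_hz = band_low_hz,
    band_high_hz = band_high_hz,
    noise_window_s = noise_window_s,
    distance_floor_m = distance_floor_m,
    seed = as.integer(seed)
  ), class = "pairspace_config")
}

#' @export
print.pairspace_config <- function(x, ...) {
  cat("pairspace run configuration\n")
  cat(sprintf("  bin length:        %g s\n", x$bin_length_s))
  cat(sprintf("  deep dive:         > %g m and > %g s\n",
              x$deep_dive_depth_m, x$deep_dive_duration_s))
  cat(sprintf("  audibility:        SNR = %g dB\n", x$snr_threshold_db))
  cat(sprintf("  noise band:        %g-%g Hz (third-octave)\n",
              x$band_low_hz, x$band_high_hz))
  cat(sprintf("  noise window:      %g s; distance floor %g m; seed %d\n",
              x$noise_window_s, x$distance_floor_m, x$seed))
  invisible(x)
}

# Stable hash of a config for result manifests: md5 of the deparsed list so
# two runs with identical settings agree byte-for-byte.
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(unclass(config)), f)
  unname(tools::md5sum(f))
}
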