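#' Time bins for a follow
#'
#' Half-open bins `[start, start + bin_length)` indexed from 0, starting at
#' the follow start. An event exactly on a boundary belongs to the later bin.
#'
#' @param follow_start,follow_end Follow window, seconds.
#' @param bin_length_s Bin length, seconds.
#' @return Data frame with `bin_index`, `t_start_s`, `t_end_s` (complete bins
#'   only).
#' @export
make_bins <- function(follow_start, follow_end, bin_length_s = 600) {
  n <- floor((follow_end - follow_start) / bin_length_s)
  if (n < 1) return(data.frame(bin_index = integer(), t_start_s = numeric(),
                               t_end_s = numeric()))
  start <- follow_start + (seq_len(n) - 1) * bin_length_s
  data.frame(bin_index = seq_len(n) - 1L, t_start_s = start,
             t_end_s = start + bin_length_s)
}

bin_of <- function(t, follow_start, bin_length_s) {
  as.integer(floor((t - follow_start) / bin_length_s))
}

#' Interpolate group positions at bin boundaries
#'
#' Positions at each bin's start and end are linearly interpolated in time
#' between the bracketing fixes, assuming straight-line travel at constant
#' speed between fixes. Bins whose boundaries fall outside the fix record
#' are marked missing and excluded downstream.
#'
#' @param fixes Data frame with `t_s`, `x_km`, `y_km`.
#' @param bins Output of [make_bins()].
#' @return `bins` augmented with `x0`, `y0`, `x1`, `y1` and logical `missing`.
#' @export
interpolate_bin_positions <- function(fixes, bins) {
  if (nrow(fixes) < 2) stop("interpolate_bin_positions: need at least 2 fixes")
  interp <- function(t) {
    ok <- t >= min(fixes$t_s) & t <= max(fixes$t_s)
    x <- y <- rep(NA_real_, length(t))
    if (any(ok)) {
      x[ok] <- stats::approx(fixes$t_s, fixes$x_km, xout = t[ok])$y
      y[ok] <- stats::approx(fixes$t_s, fixes$y_km, xout = t[ok])$y
    }
    list(x = x, y = y)
  }
  p0 <- interp(bins$t_start_s)
  p1 <- interp(bins$t_end_s)
  bins$x0 <- p0$x; bins$y0 <- p0$y; bins$x1 <- p1$x; bins$y1 <- p1$y
  bins$missing <- is.na(bins$x0) | is.na(bins$x1)
  bins
}

#' Per-bin speed, southerly speed, course, and course deviation
#'
#' Speed is the straight-line displacement rate between the interpolated bin
#' boundary positions, in km/h. Speed south is the southward component
#' (positive moving south, negative moving north); east/west or stationary
#' movement gives a value near zero. Course is the bearing in degrees
#' clockwise from north. Course deviation is the circular absolute change in
#' course from the previous bin, in [0, 180]; it is missing for the first
#' bin. A zero-displacement bin keeps the previous course (deviation 0).
#'
#' @param bins Output of [interpolate_bin_positions()].
#' @return `bins` with `speed_kmh`, `speed_south_kmh`, `course_deg`,
#'   `course_dev_deg` appended.
#' @export
compute_bin_kinematics <- function(bins) {
  n <- nrow(bins)
  speed <- speed_south <- course <- dev <- rep(NA_real_, n)
  prev_course <- NA_real_
  for (i in seq_len(n)) {
    if (bins$missing[i]) { prev_course <- NA_real_; next }
    dt_h <- (bins$t_end_s[i] - bins$t_start_s[i]) / 3600
    dx <- bins$x1[i] - bins$x0[i]
    dy <- bins$y1[i] - bins$y0[i]
    d <- sqrt(dx^2 + dy^2)
    speed[i] <- d / dt_h
    speed_south[i] <- -dy / dt_h
    if (d == 0) {
      course[i] <- prev_course   # undefined heading: carry the previous one
      dev[i] <- if (is.na(prev_course)) NA_real_ else 0
    } else {
      course[i] <- (atan2(dx, dy) * 180 / pi) %% 360
      dev[i] <- circular_diff(course[i], prev_course)
    }
    prev_course <- course[i]
  }
  bins$speed_kmh <- speed
  bins$speed_south_kmh <- speed_south
  bins$course_deg <- course
  bins$course_dev_deg <- dev
  bins
}

# absolute circular difference of two bearings, in [0, 180]
circular_diff <- function(a, b) {
  if (is.na(a) || is.na(b)) return(NA_real_)
  d <- abs(a - b) %% 360
  min(d, 360 - d)
}

#' Segment a depth record into deep dives and surface intervals
#'
#' A deep dive is a maximal excursion below the depth threshold (default
#' 10 m) lasting strictly longer than the duration threshold (default 75 s),
#' with maximum depth strictly exceeding the depth threshold. Excursion
#' boundaries are placed where the linearly interpolated depth trace crosses
#' the threshold, so results do not depend on the sampling phase. All time
#' not inside a deep dive is surface interval; the two sets tile the record.
#'
#' @param depth Data frame with `t_s`, `depth_m`.
#' @param config A [run_config()] supplying the thresholds.
#' @return List with `dives` (`t_start_s`, `t_end_s`, `duration_s`,
#'   `max_depth_m`, `mean_depth_m`) and `surface` (`t_start_s`, `t_end_s`).
#' @export
segment_dives <- function(depth, config = run_config()) {
  thr <- config$deep_dive_depth_m
  min_dur <- config$deep_dive_duration_s
  empty <- list(
    dives = data.frame(t_start_s = numeric(), t_end_s = numeric(),
                       duration_s = numeric(), max_depth_m = numeric(),
                       mean_depth_m = numeric()),
    surface = data.frame(t_start_s = numeric(), t_end_s = numeric()))
  n <- nrow(depth)
  if (n == 0) return(empty)
  t <- depth$t_s; z <- depth$depth_m
  below <- z > thr
  if (!any(below)) {
    empty$surface <- data.frame(t_start_s = t[1], t_end_s = t[n])
    return(empty)
  }

  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values)
  dives <- lapply(cand, function(k) {
    i0 <- starts[k]; i1 <- ends[k]
    # crossing times of the threshold, linearly interpolated; record edges
    # truncate an excursion already under way
    t0 <- if (i0 == 1L) t[1] else cross_time(t[i0 - 1], z[i0 - 1], t[i0], z[i0], thr)
    t1 <- if (i1 == n) t[n] else cross_time(t[i1], z[i1], t[i1 + 1], z[i1 + 1], thr)
    idx <- i0:i1
    data.frame(t_start_s = t0, t_end_s = t1, duration_s = t1 - t0,
               max_depth_m = max(z[idx]),
               mean_depth_m = excursion_mean_depth(t, z, i0, i1, t0, t1, thr))
  })
  dives <- do.call(rbind, dives)
  keep <- dives$duration_s > min_dur & dives$max_depth_m > thr
  dives <- dives[keep, , drop = FALSE]
  rownames(dives) <- NULL

  # complement of the dives tiles the record as surface intervals
  edges <- c(t[1], as.vector(rbind(dives$t_start_s, dives$t_end_s)), t[n])
  surf <- data.frame(t_start_s = edges[seq(1, length(edges) - 1, by = 2)],
                     t_end_s = edges[seq(2, length(edges), by = 2)])
  surf <- surf[surf$t_end_s > surf$t_start_s, , drop = FALSE]
  rownames(surf) <- NULL
  list(dives = dives, surface = surf)
}

# time at which the segment (t0,z0)-(t1,z1) crosses depth `thr`
cross_time <- function(t0, z0, t1, z1, thr) {
  t0 + (thr - z0) / (z1 - z0) * (t1 - t0)
}

# time-weighted mean depth over [t0, t1] of the piecewise-linear trace
excursion_mean_depth <- function(t, z, i0, i1, t0, t1, thr) {
  ts <- c(t0, t[i0:i1], t1)
  zs <- c(if (i0 == 1L) z[1] else thr, z[i0:i1], if (i1 == length(t)) z[length(t)] else thr)
  if (t1 == t0) return(zs[1])
  dt <- diff(ts)
  mid <- (zs[-1] + zs[-length(zs)]) / 2
  sum(mid * dt) / (t1 - t0)
}

#' Per-bin surface proportion and dive count
#'
#' The surface proportion of a bin is the fraction of its span not inside
#' any deep dive (a dive spanning a boundary contributes pro rata to each
#' bin). The dive count is the number of deep dives initiated (t_start)
#' within the half-open bin.
#'
#' @param segmentation Output of [segment_dives()].
#' @param bins Output of [make_bins()].
#' @return `bins` with `surface_prop`, `dive_count`, and logical
#'   `dive_missing` (bin not fully covered by the depth record).
#' @export
compute_bin_dive_metrics <- function(segmentation, bins) {
  dv <- segmentation$dives
  record <- segmentation$surface
  rec_lo <- min(c(record$t_start_s, dv$t_start_s, Inf))
  rec_hi <- max(c(record$t_end_s, dv$t_end_s, -Inf))
  overlap <- function(a0, a1, b0, b1) pmax(0, pmin(a1, b1) - pmax(a0, b0))
  bins$surface_prop <- vapply(seq_len(nrow(bins)), function(i) {
    len <- bins$t_end_s[i] - bins$t_start_s[i]
    in_dive <- if (nrow(dv)) sum(overlap(dv$t_start_s, dv$t_end_s,
                                         bins$t_start_s[i], bins$t_end_s[i])) else 0
    (len - in_dive) / len
  }, numeric(1))
  bins$dive_count <- vapply(seq_len(nrow(bins)), function(i) {
    if (!nrow(dv)) return(0L)
    sum(dv$t_start_s >= bins$t_start_s[i] & dv$t_start_s < bins$t_end_s[i])
  }, integer(1))
  bins$dive_missing <- bins$t_start_s < rec_lo - 1e-9 | bins$t_end_s > rec_hi + 1e-9
  bins
}

#' Build the per-bin movement-metric table for one or more tags
#'
#' Combines position interpolation, bin kinematics, dive segmentation, and
#' ESB counts into the six clustering variables, one row per complete
#' 10-min bin. Rows with any missing metric (notably the first bin of each
#' tag, which has no course deviation) carry `excluded = TRUE`.
#'
#' @param datasets A `tag_dataset` or list of them.
#' @param config A [run_config()].
#' @return Data frame: `tag_id`, `bin_index`, `t_start_s`, `speed_kmh`,
#'   `speed_south_kmh`, `course_deg`, `course_dev_deg`, `esb_count`,
#'   `surface_prop`, `dive_count`, `excluded`.
#' @export
build_metric_table <- function(datasets, config = run_config()) {
  if (inherits(datasets, "tag_dataset")) datasets <- list(datasets)
  rows <- lapply(datasets, function(ds) {
    bins <- make_bins(ds$follow_start, ds$follow_end, config$bin_length_s)
    if (!nrow(bins)) return(NULL)
    bins <- interpolate_bin_positions(ds$fixes, bins)
    bins <- compute_bin_kinematics(bins)
    seg <- segment_dives(ds$depth, config)
    bins <- compute_bin_dive_metrics(seg, bins)
    bins$esb_count <- vapply(seq_len(nrow(bins)), function(i) {
      sel <- ds$esb$t_s >= bins$t_start_s[i] & ds$esb$t_s < bins$t_end_s[i]
      as.integer(sum(ds$esb$count[sel]))
    }, integer(1))
    out <- data.frame(tag_id = ds$tag_id, bin_index = bins$bin_index,
                      t_start_s = bins$t_start_s, speed_kmh = bins$speed_kmh,
                      speed_south_kmh = bins$speed_south_kmh,
                      course_deg = bins$course_deg,
                      course_dev_deg = bins$course_dev_deg,
                      esb_count = bins$esb_count,
                      surface_prop = bins$surface_prop,
                      dive_count = bins$dive_count)
    out$excluded <- bins$missing | bins$dive_missing |
      is.na(out$speed_kmh) | is.na(out$course_dev_deg)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
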