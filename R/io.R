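#' Construct and validate a tag dataset
#'
#' A `tag_dataset` holds everything recorded during one focal follow of a
#' tagged adult female-calf pair: the 1-Hz (or similar) depth series from the
#' tag's pressure sensor, the land/boat position fixes, the call events with
#' received levels and peak frequencies, the ambient noise samples, and the
#' per-bin energetic surface behavior (ESB) counts.
#'
#' Timestamps are seconds (UTC epoch or follow-relative; only differences are
#' used). Positions are local planar easting/northing in kilometres with y
#' increasing northward. Rows outside `[follow_start, follow_end]` are dropped
#' and the count reported via a message.
#'
#' @param tag_id Character scalar identifying the tag/follow.
#' @param depth Data frame with columns `t_s`, `depth_m` (positive down).
#' @param fixes Data frame with columns `t_s`, `x_km`, `y_km` and optionally
#'   `source`.
#' @param calls Data frame with columns `t_s`, `age_class`
#'   (`"adult_female"`/`"calf"`), `received_level_db`, `peak_frequency_hz`,
#'   optionally `caller_depth_m`. May have zero rows.
#' @param noise Data frame with `t_s` plus either `broadband_db` or one
#'   `tob_<center_hz>_db` column per third-octave band.
#' @param esb Data frame with columns `t_s`, `count`. May have zero rows.
#' @param follow_start,follow_end Follow window in seconds; defaults to the
#'   depth-series range.
#'
#' @return An object of class `tag_dataset`.
#' @export
tag_dataset <- function(tag_id, depth, fixes, calls = NULL, noise = NULL,
                        esb = NULL, follow_start = NULL, follow_end = NULL) {
  depth <- check_schema(depth, c("t_s", "depth_m"), "depth")
  fixes <- check_schema(fixes, c("t_s", "x_km", "y_km"), "fixes")
  calls <- check_schema(calls %||% empty_calls(),
                        c("t_s", "age_class", "received_level_db",
                          "peak_frequency_hz"), "calls")
  if (is.null(calls$caller_depth_m)) calls$caller_depth_m <- NA_real_
  noise <- check_schema(noise %||% data.frame(t_s = numeric()), "t_s", "noise")
  esb <- check_schema(esb %||% data.frame(t_s = numeric(), count = integer()),
                      c("t_s", "count"), "esb")

  check_monotone(depth$t_s, "depth")
  check_monotone(fixes$t_s, "fixes")
  check_monotone(noise$t_s, "noise")
  if (any(depth$depth_m < 0)) {
    stop(sprintf("depth: negative depth at row %d (t = %g s)",
                 which(depth$depth_m < 0)[1],
                 depth$t_s[which(depth$depth_m < 0)[1]]))
  }
  bad_class <- setdiff(unique(calls$age_class), c("adult_female", "calf"))
  if (length(bad_class)) {
    stop("calls: unknown age_class value(s): ", paste(bad_class, collapse = ", "))
  }
  if (nrow(calls)) {
    if (any(calls$peak_frequency_hz <= 0)) stop("calls: peak_frequency_hz must be > 0")
    out_plaus <- calls$received_level_db < 100 | calls$received_level_db > 200
    if (any(out_plaus)) {
      stop(sprintf("calls: received_level_db outside plausible 100-200 dB at row %d",
                   which(out_plaus)[1]))
    }
    out_obs <- calls$received_level_db < 124 | calls$received_level_db > 173
    if (any(out_obs)) {
      warning(sprintf("calls: %d received level(s) outside the observed 124-173 dB span",
                      sum(out_obs)), call. = FALSE)
    }
  }

  follow_start <- follow_start %||% min(depth$t_s)
  follow_end <- follow_end %||% max(depth$t_s)
  if (!(follow_start < follow_end)) stop("follow_start must precede follow_end")

  n_before <- nrow(depth) + nrow(fixes) + nrow(calls) + nrow(noise) + nrow(esb)
  in_win <- function(d) d[d$t_s >= follow_start & d$t_s <= follow_end, , drop = FALSE]
  depth <- in_win(depth); fixes <- in_win(fixes); calls <- in_win(calls)
  noise <- in_win(noise); esb <- in_win(esb)
  n_dropped <- n_before - (nrow(depth) + nrow(fixes) + nrow(calls) +
                             nrow(noise) + nrow(esb))
  if (n_dropped > 0) {
    message(sprintf("tag %s: dropped %d row(s) outside the follow window",
                    tag_id, n_dropped))
  }

  structure(list(tag_id = as.character(tag_id), depth = depth, fixes = fixes,
                 calls = calls, noise = noise, esb = esb,
                 follow_start = follow_start, follow_end = follow_end),
            class = "tag_dataset")
}

#' @export
print.tag_dataset <- function(x, ...) {
  cat(sprintf("tag_dataset %s: %.1f min follow, %d depth samples, %d fixes, %d calls, %d noise samples\n",
              x$tag_id, (x$follow_end - x$follow_start) / 60,
              nrow(x$depth), nrow(x$fixes), nrow(x$calls), nrow(x$noise)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

empty_calls <- function() {
  data.frame(t_s = numeric(), age_class = character(),
             received_level_db = numeric(), peak_frequency_hz = numeric(),
             caller_depth_m = numeric())
}

check_schema <- function(df, required, name) {
  if (!is.data.frame(df)) stop(name, ": expected a data frame")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing mandatory column(s): %s", name,
                 paste(missing, collapse = ", ")))
  }
  df
}

check_monotone <- function(t, name) {
  if (length(t) > 1 && any(diff(t) <= 0)) {
    stop(sprintf("%s: timestamps not strictly increasing at row %d",
                 name, which(diff(t) <= 0)[1] + 1L))
  }
}

#' Load one or more tag datasets from CSV files
#'
#' Reads the on-disk schema (`depth.csv`, `fixes.csv`, `calls.csv`,
#' `noise.csv`, `esb.csv`, optionally `follows.csv` with columns `tag_id`,
#' `follow_start_s`, `follow_end_s`) from a directory, splits by `tag_id`,
#' and validates each follow via [tag_dataset()].
#'
#' @param dir Directory containing the CSV files.
#' @param config A [run_config()].
#' @return A named list of `tag_dataset` objects (one per tag).
#' @export
load_tag_datasets <- function(dir, config = run_config()) {
  read_req <- function(fname, required) {
    path <- file.path(dir, fname)
    if (!file.exists(path)) stop("missing input file: ", path)
    check_schema(utils::read.csv(path), c("tag_id", required), fname)
  }
  depth <- read_req("depth.csv", c("t_s", "depth_m"))
  fixes <- read_req("fixes.csv", c("t_s", "x_km", "y_km"))
  calls <- if (file.exists(file.path(dir, "calls.csv"))) {
    read_req("calls.csv", c("t_s", "age_class", "received_level_db",
                            "peak_frequency_hz"))
  }
  noise <- if (file.exists(file.path(dir, "noise.csv"))) read_req("noise.csv", "t_s")
  esb <- if (file.exists(file.path(dir, "esb.csv"))) read_req("esb.csv", c("t_s", "count"))
  follows <- if (file.exists(file.path(dir, "follows.csv"))) {
    utils::read.csv(file.path(dir, "follows.csv"))
  }

  ids <- sort(unique(depth$tag_id))
  out <- lapply(ids, function(id) {
    pick <- function(df) if (is.null(df)) NULL else df[df$tag_id == id,
                                                       setdiff(names(df), "tag_id"),
                                                       drop = FALSE]
    fs <- fe <- NULL
    if (!is.null(follows) && id %in% follows$tag_id) {
      row <- follows[follows$tag_id == id, ][1, ]
      fs <- row$follow_start_s; fe <- row$follow_end_s
    }
    tag_dataset(id, depth = pick(depth), fixes = pick(fixes),
                calls = pick(calls), noise = pick(noise), esb = pick(esb),
                follow_start = fs, follow_end = fe)
  })
  names(out) <- ids
  out
}

#' Write result tables to CSV with a JSON manifest
#'
#' @param tables Named list of data frames.
#' @param out_dir Output directory (created if needed).
#' @param config A [run_config()]; its hash and seed are recorded.
#' @return Invisibly, the manifest (also written to `manifest.json`).
#' @export
write_results <- function(tables, out_dir, config = run_config()) {
  stopifnot(is.list(tables))
  if (length(tables) && is.null(names(tables))) stop("tables must be named")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  entries <- lapply(names(tables), function(nm) {
    fn <- paste0(nm, ".csv")
    utils::write.csv(tables[[nm]], file.path(out_dir, fn), row.names = FALSE)
    list(file = fn, rows = nrow(tables[[nm]]))
  })
  manifest <- list(files = entries, config_hash = config_hash(config),
                   seed = config$seed)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Load a transmission-loss coefficient table
#'
#' Reads per-octave-band piecewise transmission-loss coefficients: intercept
#' `a_db` (TL at the 1-m reference distance), near slope `b_near` and far
#' slope `b_far` (dB per decade of distance), and the crossover distance
#' `crossover_m` where the slope changes. A band with a single slope uses
#' `crossover_m = Inf`. With no path, a synthetic shallow-water table bundled
#' with the package is returned; it mimics the structure of site-specific
#' measured coefficients (spherical-like spreading near the source, then a
#' reduced or enhanced rate beyond a few hundred metres) and is intended for
#' simulation and testing only, not for inference about any real site.
#'
#' @param path CSV with columns `center_hz`, `a_db`, `b_near`, `b_far`,
#'   `crossover_m`, or `NULL` for the bundled synthetic table.
#' @return A data frame of class `tl_bands`.
#' @export
load_tl_bands <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "tl_bands_synthetic.csv", package = "pairspace")
  }
  tab <- check_schema(utils::read.csv(path),
                      c("center_hz", "a_db", "b_near", "b_far", "crossover_m"),
                      "tl_bands")
  tab <- tab[order(tab$center_hz), , drop = FALSE]
  if (any(tab$b_near <= 0) || any(tab$b_far <= 0)) {
    stop("tl_bands: slopes must be positive (TL nondecreasing in distance)")
  }
  if (any(tab$crossover_m < 1)) stop("tl_bands: crossover must be >= 1 m")
  class(tab) <- c("tl_bands", "data.frame")
  tab
}
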