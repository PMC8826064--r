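#' Segment dives for every tag and pool them
#'
#' @param datasets Named list of [tag_dataset()] objects.
#' @param config A [run_config()].
#' @return Data frame of deep dives with `tag_id` prepended.
#' @export
segment_all_dives <- function(datasets, config = run_config()) {
  rows <- lapply(datasets, function(ds) {
    dv <- segment_dives(ds$depth, config)$dives
    if (!nrow(dv)) return(NULL)
    cbind(tag_id = ds$tag_id, dv)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  if (is.null(out)) out <- data.frame(tag_id = character(), t_start_s = numeric(),
                                      t_end_s = numeric(), duration_s = numeric(),
                                      max_depth_m = numeric(),
                                      mean_depth_m = numeric())
  out
}

collect_calls <- function(datasets) {
  do.call(rbind, c(lapply(datasets, function(ds) {
    if (!nrow(ds$calls)) return(NULL)
    cbind(tag_id = ds$tag_id, ds$calls)
  }), make.row.names = FALSE))
}

#' Run the full female-calf pair analysis
#'
#' Chains the pipeline: per-bin movement metrics, standardization,
#' cluster-count selection and k-means state labeling, dive-parameter
#' models, per-state call rates with the negative-binomial rate model,
#' the received-level model, and detection-distance estimation with the
#' state comparison.
#'
#' @param datasets Named list of [tag_dataset()] objects.
#' @param tl_bands A [load_tl_bands()] table (default: the bundled
#'   synthetic coefficients).
#' @param config A [run_config()].
#' @param k Cluster count; `NULL` (default) selects it by the index vote.
#' @return List with elements `metrics`, `selection`, `clustering`,
#'   `dives`, `dive_models`, `rates`, `rate_models`, `level_model`,
#'   `detections`, `distance_model`, `surface`.
#' @export
run_pair_analysis <- function(datasets, tl_bands = load_tl_bands(),
                              config = run_config(), k = NULL) {
  follow_starts <- vapply(datasets, function(d) d$follow_start, numeric(1))
  names(follow_starts) <- vapply(datasets, function(d) d$tag_id, character(1))

  metrics <- build_metric_table(datasets, config)
  std <- standardize_metrics(metrics)
  selection <- if (is.null(k)) {
    select_cluster_count(std$z, seed = config$seed)
  }
  k_use <- if (is.null(k)) selection$k else k
  clustering <- cluster_and_label(std, metrics, k = k_use, seed = config$seed)
  assignments <- clustering$assignments

  dives <- segment_all_dives(datasets, config)
  dive_models <- NULL
  if (k_use == 2 && nrow(dives) && length(unique(dives$tag_id)) >= 2) {
    dives <- assign_event_states(dives, assignments, follow_starts,
                                 config$bin_length_s, t_col = "t_start_s")
    with_state <- dives[!is.na(dives$state), , drop = FALSE]
    if (length(unique(with_state$tag_id)) >= 2 &&
        length(unique(with_state$state)) == 2) {
      dive_models <- rank_dive_models(with_state)
    }
  }

  calls <- collect_calls(datasets)
  rates <- rate_models <- level_model <- NULL
  detections <- distance_model <- surface <- NULL
  if (!is.null(calls) && nrow(calls) && k_use == 2) {
    rates <- compute_call_rates(calls, assignments, follow_starts,
                                config$bin_length_s)
    counts <- bin_call_counts(calls, assignments, follow_starts,
                              config$bin_length_s)
    rate_models <- lapply(stats::setNames(nm = c("adult_female", "calf")),
                          function(cls) {
      fit_rate_model(counts[counts$age_class == cls, , drop = FALSE])
    })
    af <- assign_event_states(calls[calls$age_class == "adult_female", ,
                                    drop = FALSE],
                              assignments, follow_starts, config$bin_length_s)
    if (sum(!is.na(af$state)) >= 4) level_model <- fit_level_model(af)

    detections <- do.call(rbind, c(lapply(datasets, function(ds) {
      if (!nrow(ds$calls)) return(NULL)
      est <- estimate_detection_distances(ds$calls, ds$noise, tl_bands, config)
      cbind(tag_id = ds$tag_id, est)
    }), make.row.names = FALSE))
    detections <- assign_event_states(detections, assignments, follow_starts,
                                      config$bin_length_s)
    usable <- detections[!is.na(detections$distance_m) &
                           !is.na(detections$state) & !detections$floored, ,
                         drop = FALSE]
    if (nrow(usable) >= 4 && length(unique(usable$tag_id)) >= 2 &&
        length(unique(usable$state)) == 2) {
      distance_model <- fit_detection_distance_model(detections)
    }
    if (any(!is.na(detections$distance_m))) {
      surface <- distance_surface_summary(detections)
    }
  }

  list(metrics = metrics, selection = selection, clustering = clustering,
       dives = dives, dive_models = dive_models, rates = rates,
       rate_models = rate_models, level_model = level_model,
       detections = detections, distance_model = distance_model,
       surface = surface)
}
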