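METRIC_VARS <- c("speed_kmh", "speed_south_kmh", "course_dev_deg",
                 "esb_count", "surface_prop", "dive_count")

#' Standardize the six movement metrics
#'
#' Centers each clustering variable to mean 0 and scales it to unit sample
#' SD over the included bins, so variables measured in km/h, degrees, and
#' counts weigh equally in the k-means distance.
#'
#' @param metrics Output of [build_metric_table()].
#' @return List: `z` (standardized matrix over included bins), `center`,
#'   `scale`, and `keys` (tag_id/bin_index of the included rows).
#' @export
standardize_metrics <- function(metrics) {
  inc <- metrics[!metrics$excluded, , drop = FALSE]
  if (nrow(inc) < 2) stop("standardize_metrics: need at least 2 included bins")
  X <- as.matrix(inc[, METRIC_VARS])
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("standardize_metrics: constant column(s): ",
         paste(METRIC_VARS[sds == 0], collapse = ", "))
  }
  mus <- colMeans(X)
  z <- scale(X, center = mus, scale = sds)
  list(z = z, center = mus, scale = sds,
       keys = inc[, c("tag_id", "bin_index")])
}

#' Invert standardization
#'
#' @param std Output of [standardize_metrics()].
#' @param z Standardized matrix (defaults to `std$z`).
#' @return Matrix on the original measurement scales.
#' @export
destandardize_metrics <- function(std, z = std$z) {
  out <- sweep(sweep(unclass(z), 2, std$scale, `*`), 2, std$center, `+`)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  out
}

#' Choose the number of k-means clusters by a multi-index vote
#'
#' Evaluates four internal validity indices over a range of candidate k --
#' mean silhouette width, the Calinski-Harabasz pseudo-F, the Davies-Bouldin
#' index, and the gap statistic (first-SE rule) -- and returns the
#' majority-vote k, breaking ties toward the smallest k. All per-index votes
#' are returned so disagreement between indices is visible.
#'
#' @param z Standardized metric matrix.
#' @param k_range Candidate cluster counts (default 2..8).
#' @param seed Integer seed for the k-means restarts and gap bootstraps.
#' @param n_restarts k-means restarts per k.
#' @param gap_B Bootstrap reference sets for the gap statistic.
#' @return List: `k`, `index_votes` (named integer vector), `index_values`.
#' @export
select_cluster_count <- function(z, k_range = 2:8, seed = 1L,
                                 n_restarts = 25, gap_B = 50) {
  n <- nrow(z)
  if (n < 4) stop("select_cluster_count: need at least 4 points")
  if (n <= max(k_range)) {
    warning("select_cluster_count: shrinking k_range to n - 1")
    k_range <- k_range[k_range < n]
  }
  d <- stats::dist(z)
  fits <- lapply(k_range, function(k) {
    set.seed(seed + k)
    stats::kmeans(z, centers = k, nstart = n_restarts, iter.max = 100)
  })
  sil <- vapply(seq_along(k_range), function(i) {
    mean(cluster::silhouette(fits[[i]]$cluster, d)[, "sil_width"])
  }, numeric(1))
  ch <- vapply(seq_along(k_range), function(i) {
    calinski_harabasz(fits[[i]], n)
  }, numeric(1))
  db <- vapply(seq_along(k_range), function(i) {
    davies_bouldin(z, fits[[i]])
  }, numeric(1))
  set.seed(seed)
  gap <- cluster::clusGap(z, FUN = function(x, k) {
    stats::kmeans(x, centers = k, nstart = n_restarts, iter.max = 100)
  }, K.max = max(k_range), B = gap_B, verbose = FALSE)
  gtab <- gap$Tab[k_range, , drop = FALSE]
  gap_k <- k_range[cluster::maxSE(gtab[, "gap"], gtab[, "SE.sim"],
                                  method = "firstSEmax")]

  votes <- c(silhouette = k_range[which.max(sil)],
             calinski_harabasz = k_range[which.max(ch)],
             davies_bouldin = k_range[which.min(db)],
             gap = gap_k)
  tab <- table(votes)
  winners <- as.integer(names(tab)[tab == max(tab)])
  list(k = min(winners), index_votes = votes,
       index_values = list(k_range = k_range, silhouette = sil,
                           calinski_harabasz = ch, davies_bouldin = db,
                           gap = gtab[, "gap"]))
}

calinski_harabasz <- function(fit, n) {
  k <- length(fit$size)
  (fit$betweenss / (k - 1)) / (fit$tot.withinss / (n - k))
}

davies_bouldin <- function(z, fit) {
  k <- length(fit$size)
  centers <- fit$centers
  s <- vapply(seq_len(k), function(j) {
    pts <- z[fit$cluster == j, , drop = FALSE]
    mean(sqrt(rowSums(sweep(pts, 2, centers[j, ])^2)))
  }, numeric(1))
  m <- as.matrix(stats::dist(centers))
  r <- vapply(seq_len(k), function(j) {
    max(vapply(setdiff(seq_len(k), j),
               function(l) (s[j] + s[l]) / m[j, l], numeric(1)))
  }, numeric(1))
  mean(r)
}

#' Cluster bins and label the two behavioral states
#'
#' Runs seeded multi-restart k-means on the standardized metrics. For k = 2
#' the cluster with the lower mean raw swimming speed is labeled
#' `resting_milling` and the other `travelling`; for other k the raw cluster
#' indices are returned unlabeled.
#'
#' @param std Output of [standardize_metrics()].
#' @param metrics The raw metric table (for the speed-based labeling).
#' @param k Number of clusters.
#' @param seed Integer seed.
#' @param n_restarts k-means restarts (>= 25).
#' @return List: `fit` (the `kmeans` object), and `assignments`, a data
#'   frame with `tag_id`, `bin_index`, `cluster`, and (k = 2 only) `state`.
#' @export
cluster_and_label <- function(std, metrics, k = 2, seed = 1L, n_restarts = 25) {
  if (!nrow(std$z)) stop("cluster_and_label: empty input")
  set.seed(seed)
  fit <- stats::kmeans(std$z, centers = k, nstart = max(25, n_restarts),
                       iter.max = 100)
  out <- cbind(std$keys, cluster = fit$cluster)
  if (k == 2) {
    inc <- merge(out, metrics[, c("tag_id", "bin_index", "speed_kmh")],
                 by = c("tag_id", "bin_index"), sort = FALSE)
    mean_speed <- tapply(inc$speed_kmh, inc$cluster, mean)
    resting <- as.integer(names(mean_speed)[which.min(mean_speed)])
    out$state <- ifelse(out$cluster == resting, "resting_milling", "travelling")
  }
  rownames(out) <- NULL
  list(fit = fit, assignments = out)
}

#' Rank binomial mixed models of behavioral state on dive parameters
#'
#' Fits logistic mixed models (random intercept per tag, Laplace ML) of the
#' binary state of the bin in which each adult-female dive started, over all
#' non-empty subsets of {duration, mean depth, max depth}, and ranks them by
#' AIC. Wald z p-values are reported for each fit.
#'
#' @param dives Data frame with `tag_id`, `duration_s`, `mean_depth_m`,
#'   `max_depth_m`, and `state` (`"resting_milling"`/`"travelling"`).
#' @return Data frame sorted by AIC: `predictor_set`, `aic`, plus a
#'   `fits` attribute with the fitted models and a `coefficients` list
#'   column of per-term estimate/SE/z/p tables.
#' @export
rank_dive_models <- function(dives) {
  stopifnot(all(c("tag_id", "duration_s", "mean_depth_m", "max_depth_m",
                  "state") %in% names(dives)))
  if (length(unique(dives$tag_id)) < 2) {
    stop("rank_dive_models: need dives from at least 2 tags")
  }
  dives$y <- as.integer(dives$state == "travelling")
  preds <- c("duration_s", "mean_depth_m", "max_depth_m")
  sets <- unlist(lapply(seq_along(preds), function(m) {
    utils::combn(preds, m, simplify = FALSE)
  }), recursive = FALSE)

  # fit on standardized predictors for numerical stability; AIC and Wald
  # p-values are invariant, and coefficients are mapped back to per-unit scale
  pred_sd <- vapply(preds, function(v) stats::sd(dives[[v]]), numeric(1))
  for (v in preds) dives[[paste0(v, "_z")]] <- as.numeric(scale(dives[[v]]))

  quiet_glmer <- function(f, nAGQ = 1L) {
    withCallingHandlers(
      lme4::glmer(f, data = dives, family = stats::binomial(), nAGQ = nAGQ),
      warning = function(w) invokeRestart("muffleWarning"))
  }
  fits <- lapply(sets, function(vars) {
    f <- stats::reformulate(c(paste0(vars, "_z"), "(1 | tag_id)"),
                            response = "y")
    tryCatch(quiet_glmer(f),
             error = function(e) tryCatch(quiet_glmer(f, nAGQ = 0L),
                                          error = function(e2) NULL))
  })
  res <- data.frame(
    predictor_set = vapply(sets, paste, character(1), collapse = "+"),
    aic = vapply(fits, function(f) if (is.null(f)) Inf else stats::AIC(f),
                 numeric(1)))
  res$coefficients <- lapply(fits, function(f) {
    if (is.null(f)) {
      return(data.frame(term = NA_character_, estimate = NA_real_,
                        se = NA_real_, z = NA_real_, p = NA_real_))
    }
    co <- stats::coef(summary(f))
    term <- sub("_z$", "", rownames(co))
    fac <- ifelse(term %in% preds, pred_sd[term], 1)
    data.frame(term = term, estimate = co[, "Estimate"] / fac,
               se = co[, "Std. Error"] / fac, z = co[, "z value"],
               p = co[, "Pr(>|z|)"], row.names = NULL)
  })
  sep_flag <- vapply(seq_along(fits), function(i) {
    is.null(fits[[i]]) ||
      any(abs(lme4::fixef(fits[[i]])) > 15, na.rm = TRUE)
  }, logical(1))
  if (any(sep_flag)) {
    warning("rank_dive_models: possible complete separation in ",
            sum(sep_flag), " model(s) (failed fit or very large coefficients)")
  }
  ord <- order(res$aic)
  res <- res[ord, ]
  rownames(res) <- NULL
  attr(res, "fits") <- fits[ord]
  res
}

#' Attach the behavioral state of the containing bin to events
#'
#' @param events Data frame with `tag_id` and a time column `t_col`.
#' @param assignments The `assignments` element of [cluster_and_label()].
#' @param follow_starts Named vector of follow start times per tag.
#' @param bin_length_s Bin length, seconds.
#' @param t_col Name of the event-time column.
#' @return `events` with `bin_index` and `state` joined; events in bins
#'   without a state (excluded bins) get `NA`.
#' @export
assign_event_states <- function(events, assignments, follow_starts,
                                bin_length_s = 600, t_col = "t_s") {
  events$bin_index <- bin_of(events[[t_col]],
                             follow_starts[as.character(events$tag_id)],
                             bin_length_s)
  merge(events, assignments[, c("tag_id", "bin_index", "state")],
        by = c("tag_id", "bin_index"), all.x = TRUE, sort = FALSE)
}
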