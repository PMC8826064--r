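#' Per-state, per-age-class call rates
#'
#' Calls are assigned to 10-min bins and the bins' behavioral states; the
#' rate for each (age class, state) is the call count divided by the total
#' hours spent in that state. Calf rates are flagged as minimum estimates:
#' the tag sits on the female, so calls from a distant calf can be missed.
#'
#' @param calls Data frame with `tag_id`, `t_s`, `age_class`.
#' @param assignments The `assignments` element of [cluster_and_label()].
#' @param follow_starts Named vector of follow start times per tag.
#' @param bin_length_s Bin length, seconds.
#' @return Data frame: `age_class`, `state`, `n_calls`, `hours`,
#'   `rate_per_h`, `is_minimum`.
#' @export
compute_call_rates <- function(calls, assignments, follow_starts,
                               bin_length_s = 600) {
  calls <- assign_event_states(calls, assignments, follow_starts, bin_length_s)
  calls <- calls[!is.na(calls$state), , drop = FALSE]
  hours <- tapply(rep(bin_length_s / 3600, nrow(assignments)),
                  assignments$state, sum)
  grid <- expand.grid(age_class = c("adult_female", "calf"),
                      state = names(hours), stringsAsFactors = FALSE)
  grid$n_calls <- mapply(function(a, s) {
    sum(calls$age_class == a & calls$state == s)
  }, grid$age_class, grid$state)
  grid$hours <- as.numeric(hours[grid$state])
  grid$rate_per_h <- ifelse(grid$hours > 0, grid$n_calls / grid$hours, NA_real_)
  grid$is_minimum <- grid$age_class == "calf"
  if (any(grid$hours == 0)) {
    warning("compute_call_rates: a state has zero hours; its rate is undefined")
  }
  grid
}

#' Per-bin call counts with exposure, ready for the rate model
#'
#' @inheritParams compute_call_rates
#' @return One row per (included bin, age class): `tag_id`, `bin_index`,
#'   `state`, `age_class`, `count`, `exposure_h`.
#' @export
bin_call_counts <- function(calls, assignments, follow_starts,
                            bin_length_s = 600) {
  calls <- assign_event_states(calls, assignments, follow_starts, bin_length_s)
  out <- merge(expand.grid(age_class = c("adult_female", "calf"),
                           stringsAsFactors = FALSE),
               assignments[, c("tag_id", "bin_index", "state")])
  key <- function(d) paste(d$tag_id, d$bin_index, d$age_class)
  cnt <- table(key(calls))
  out$count <- as.integer(cnt[key(out)])
  out$count[is.na(out$count)] <- 0L
  out$exposure_h <- bin_length_s / 3600
  out[order(out$tag_id, out$bin_index, out$age_class), ]
}

#' Negative-binomial mixed model of call counts by behavioral state
#'
#' Fits counts per 10-min bin with a log link, a log exposure offset (time
#' in decimal hours), a random intercept per group (tag), and the quadratic
#' negative-binomial mean-variance relation Var = mu + mu^2/theta, which
#' absorbs overdispersion relative to Poisson. Least-squares means are
#' back-transformed to calls/h; the travelling - resting contrast is
#' reported on the log scale with a Wald z test.
#'
#' @param counts Output of [bin_call_counts()], filtered to one age class.
#' @return List of class `rate_model`: `model`, `rates` (state LS-means in
#'   calls/h with SE), `contrast` (log-rate difference, SE, z, p), `theta`.
#' @export
fit_rate_model <- function(counts) {
  stopifnot(all(c("tag_id", "state", "count", "exposure_h") %in% names(counts)))
  if (any(counts$exposure_h <= 0)) {
    warning("fit_rate_model: dropping rows with zero exposure")
    counts <- counts[counts$exposure_h > 0, , drop = FALSE]
  }
  if (length(unique(counts$tag_id)) < 2) stop("fit_rate_model: need >= 2 groups")
  counts$state <- factor(counts$state,
                         levels = c("resting_milling", "travelling"))
  if (all(counts$count == 0)) {
    warning("fit_rate_model: all counts zero; boundary fit")
  }
  model <- glmmTMB::glmmTMB(
    count ~ state + (1 | tag_id) + offset(log(exposure_h)),
    family = glmmTMB::nbinom2(), data = counts)
  emm <- emmeans::emmeans(model, ~state, offset = 0, type = "response")
  rates <- as.data.frame(emm)
  names(rates)[names(rates) == "response"] <- "rate_per_h"
  con <- state_contrast(emm)
  theta <- stats::sigma(model)   # glmmTMB nbinom2 dispersion = theta
  structure(list(model = model, rates = rates, contrast = con, theta = theta),
            class = "rate_model")
}

#' Linear mixed model of adult-female received call level by state
#'
#' Received level on the tagged female proxies source level (tags sit a
#' similar distance from the larynx), so a level shift between states would
#' indicate a Lombard-like adjustment. Fit by REML with a random intercept
#' per tag; the state contrast uses a t reference distribution with
#' n_groups - 1 degrees of freedom.
#'
#' @param calls Data frame with `tag_id`, `received_level_db`, `state`;
#'   adult-female calls only (calf received levels confound caller distance
#'   with source level and are excluded from this model).
#' @return List of class `level_model`: `model`, `means` (state LS-means,
#'   dB re 1 uPa), `contrast` (difference, SE, t, df, p).
#' @export
fit_level_model <- function(calls) {
  stopifnot(all(c("tag_id", "received_level_db", "state") %in% names(calls)))
  calls <- calls[!is.na(calls$state), , drop = FALSE]
  calls$state <- factor(calls$state,
                        levels = c("resting_milling", "travelling"))
  present <- table(calls$state) > 0
  if (!all(present)) {
    warning("fit_level_model: state(s) with no calls; contrast undefined")
  }
  model <- lme4::lmer(received_level_db ~ state + (1 | tag_id), data = calls,
                      REML = TRUE)
  df_resid <- length(unique(calls$tag_id)) - 1
  emm <- emmeans::emmeans(model, ~state, lmer.df = "asymptotic")
  emm <- update(emm, df = df_resid)
  means <- as.data.frame(emm)
  con <- if (all(present)) state_contrast(emm) else NULL
  structure(list(model = model, means = means, contrast = con, df = df_resid),
            class = "level_model")
}

#' Pairwise state contrasts with multivariate-t adjustment
#'
#' Least-squares-means pairwise comparisons adjusted by the multivariate-t
#' method, which accounts for the correlation structure of the estimates.
#' With a single contrast (a 2-level factor) the adjusted p equals the
#' unadjusted p.
#'
#' @param emm An `emmGrid` (from [emmeans::emmeans()]) over the state factor.
#' @return Data frame of contrasts: `contrast`, `estimate`, `se`, statistic
#'   (`z` or `t` with `df`), `p`.
#' @export
state_contrast <- function(emm) {
  con <- emmeans::contrast(emm, method = "revpairwise", adjust = "mvt")
  out <- as.data.frame(summary(con))
  names(out)[names(out) == "SE"] <- "se"
  names(out)[names(out) == "p.value"] <- "p"
  # response-scale emmGrids report a ratio; keep the log-scale estimate too
  if ("ratio" %in% names(out)) out$log_estimate <- log(out$ratio)
  out
}
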