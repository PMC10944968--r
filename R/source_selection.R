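#' Relative-change baseline correction of power maps
#'
#' `(power - baseline) / baseline`, elementwise, with the baseline averaged
#' over trials beforehand. Because power is nonnegative the corrected values
#' are bounded below by -1.
#'
#' @param power numeric array of power values; first dimensions index
#'   sources/time/frequency, the last indexes trials.
#' @param baseline_power array of baseline-epoch power with the same layout
#'   (trial-resolved; averaged internally) or already trial-averaged.
#' @return corrected array, same shape as `power`.
#' @export
baseline_correct <- function(power, baseline_power) {
  dp <- dim(power)
  if (!is.null(dim(baseline_power)) &&
      length(dim(baseline_power)) == length(dp)) {
    nd <- length(dp)
    baseline_power <- apply(baseline_power, seq_len(nd - 1), mean)
  }
  if (any(baseline_power <= 0)) stop("baseline power must be positive")
  sweep(sweep(power, seq_along(dim(baseline_power)), baseline_power, "-"),
        seq_along(dim(baseline_power)), baseline_power, "/")
}

#' Massive univariate one-way ANOVA over a time-frequency power map
#'
#' Fixed-effects one-way F statistic with trial type as the factor, computed
#' independently in every (source, time, frequency) cell.
#'
#' @param power array `[n_sources, n_time, n_freq, n_trials]`.
#' @param trial_type factor (or coercible) of length `n_trials` with at
#'   least 2 trials per level.
#' @return array `[n_sources, n_time, n_freq]` of F statistics with
#'   attributes `df1`, `df2`.
#' @export
tf_anova <- function(power, trial_type) {
  stopifnot(length(dim(power)) == 4)
  trial_type <- as.factor(trial_type)
  stopifnot(dim(power)[4] == length(trial_type))
  counts <- table(trial_type)
  if (any(counts < 2))
    stop("trial type '", names(counts)[which.min(counts)],
         "' has fewer than 2 trials")
  k <- nlevels(trial_type)
  N <- length(trial_type)
  d <- dim(power)
  X <- matrix(power, ncol = N)            # cells x trials
  grand <- rowMeans(X)
  ss_between <- 0
  ss_within <- 0
  for (lv in levels(trial_type)) {
    sel <- trial_type == lv
    gm <- rowMeans(X[, sel, drop = FALSE])
    ss_between <- ss_between + sum(sel) * (gm - grand)^2
    ss_within <- ss_within + rowSums((X[, sel, drop = FALSE] - gm)^2)
  }
  F <- (ss_between / (k - 1)) / (ss_within / (N - k))
  out <- array(F, d[1:3])
  attr(out, "df1") <- k - 1
  attr(out, "df2") <- N - k
  out
}

#' Select one source per region of interest by collapsed F statistic
#'
#' Sums the (uncorrected) F statistics over all time-frequency cells per
#' source and returns, within each ROI's candidate set, the source with the
#' largest collapsed F. Ties are broken deterministically toward the lowest
#' source index. ROIs listed in `bilateral_rois` are selected once over the
#' union of their candidates (e.g. a midline region pooled across
#' hemispheres).
#'
#' @param F_maps array `[n_sources, n_time, n_freq]` from [tf_anova()].
#' @param rois named list of integer candidate source indices per ROI.
#' @param bilateral_rois character vector naming ROI pairs already merged in
#'   `rois` (informational; kept in the output).
#' @return data frame with `roi`, `source`, `collapsed_F`.
#' @export
select_sources <- function(F_maps, rois, bilateral_rois = character()) {
  stopifnot(length(dim(F_maps)) == 3, length(rois) >= 1)
  collapsed <- apply(F_maps, 1, sum)
  out <- lapply(names(rois), function(rn) {
    cand <- sort(unique(rois[[rn]]))
    if (length(cand) == 0) stop("ROI '", rn, "' has no candidate sources")
    if (any(cand < 1 | cand > length(collapsed)))
      stop("ROI '", rn, "' references sources outside the F map")
    f <- collapsed[cand]
    best <- cand[which.max(f)]    # which.max takes the first maximum: ties
                                  # resolve to the lowest index
    data.frame(roi = rn, source = best, collapsed_F = max(f),
               bilateral = rn %in% bilateral_rois)
  })
  do.call(rbind, out)
}

#' Synthetic source-level time-frequency power maps
#'
#' Generates lognormal baseline-corrected-style power observations on the
#' standard analysis grid (31 windows of 0.5 s in 0.05 s steps; 2-100 Hz in
#' 2 Hz steps by default), i.i.d. across trials within trial type, with an
#' optional multiplicative effect planted at one source for one trial type
#' over a time-frequency patch.
#'
#' @param n_sources number of candidate sources.
#' @param n_trials_per_type trials per trial-type level.
#' @param trial_types labels of the factor levels.
#' @param n_time,n_freq grid size (defaults 31 x 50).
#' @param effect_source,effect_type planted effect location (source index
#'   and trial-type label); `NULL` for a global-null map.
#' @param effect_size multiplicative power increase of the planted effect.
#' @param effect_cells proportion of TF cells carrying the effect (a
#'   contiguous block starting at the grid origin).
#' @param noise_sd lognormal sigma of the power observations.
#' @param seed integer seed.
#' @return list with `power` (`[source, time, freq, trial]` array),
#'   `trial_type` factor, and `baseline` (matching positive baseline map).
#' @export
simulate_tf_power <- function(n_sources = 8, n_trials_per_type = 30,
                              trial_types = c("high_accuracy",
                                              "low_accuracy", "swap"),
                              n_time = 31, n_freq = 50,
                              effect_source = NULL, effect_type = NULL,
                              effect_size = 0.5, effect_cells = 0.25,
                              noise_sd = 0.5, seed = 1) {
  k <- length(trial_types)
  n_trials <- k * n_trials_per_type
  trial_type <- factor(rep(trial_types, each = n_trials_per_type),
                       levels = trial_types)
  with_substream(seed, "tf_power", {
    power <- array(
      exp(stats::rnorm(n_sources * n_time * n_freq * n_trials, 0, noise_sd)),
      c(n_sources, n_time, n_freq, n_trials))
    if (!is.null(effect_source)) {
      stopifnot(effect_type %in% trial_types)
      nt <- max(1, round(n_time * sqrt(effect_cells)))
      nf <- max(1, round(n_freq * sqrt(effect_cells)))
      sel <- which(trial_type == effect_type)
      power[effect_source, seq_len(nt), seq_len(nf), sel] <-
        power[effect_source, seq_len(nt), seq_len(nf), sel] *
        (1 + effect_size)
    }
    baseline <- array(
      exp(stats::rnorm(n_sources * n_time * n_freq, 0, noise_sd / 4)),
      c(n_sources, n_time, n_freq))
    list(power = power, trial_type = trial_type, baseline = baseline)
  })
}
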