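#' Specification for a multi-subject, multi-condition spectral dataset
#'
#' Ground-truth generator for the group analysis: each subject's extrinsic
#' connectivity deviates from the default by independent Gaussian draws in
#' log-scaling units, and each non-baseline condition additionally scales
#' the modulated edges by the ground-truth condition effects. Observed data
#' are epoched timecourses from the stochastic network integration plus
#' observation noise.
#'
#' @param n_subjects number of subjects.
#' @param arch a [network_architecture()].
#' @param params base [microcircuit_params()] (defaults for `arch`).
#' @param between_subject_sd SD of per-subject log-scaling deviations on the
#'   extrinsic (A) parameters.
#' @param condition_effects named list: condition label -> named numeric
#'   vector of ground-truth B values over edge labels (see [edge_labels]
#'   format `"from->to"`). Conditions not listed behave as baseline. Only
#'   `b_mask` edges may appear.
#' @param n_epochs,epoch_length_s,sampling_rate_hz sampling layout per
#'   subject and condition.
#' @param seed root seed.
#' @param max_redraws resampling attempts for unstable subject draws.
#' @return object of class `group_sim_spec`.
#' @export
group_sim_spec <- function(n_subjects, arch, params = microcircuit_params(arch),
                           between_subject_sd = 0.1,
                           condition_effects = list(),
                           n_epochs = 32, epoch_length_s = 0.8,
                           sampling_rate_hz = 400, seed = 1,
                           max_redraws = 5) {
  el <- edge_labels(arch)
  masked <- el[arch$edges$b_mask]
  for (cond in names(condition_effects)) {
    bad <- setdiff(names(condition_effects[[cond]]), masked)
    if (length(bad) > 0)
      stop("condition effects on edges outside b_mask: ",
           paste(bad, collapse = ", "))
  }
  structure(list(n_subjects = n_subjects, arch = arch, params = params,
                 between_subject_sd = between_subject_sd,
                 condition_effects = condition_effects,
                 n_epochs = n_epochs, epoch_length_s = epoch_length_s,
                 sampling_rate_hz = sampling_rate_hz, seed = seed,
                 max_redraws = max_redraws),
            class = "group_sim_spec")
}

#' Simulate the group dataset
#'
#' @param spec a [group_sim_spec()].
#' @param conditions condition labels to realize (baseline is always
#'   included first).
#' @return list with `subjects` (per subject: `theta_true`, and per
#'   condition an epoched timecourse array) and `spec`.
#' @export
simulate_group_spectra <- function(spec,
                                   conditions = union("baseline",
                                                      names(spec$condition_effects))) {
  arch <- spec$arch
  el <- edge_labels(arch)
  a_names <- paste0("A:", el)
  masked <- which(arch$edges$b_mask)
  subjects <- vector("list", spec$n_subjects)
  duration <- spec$n_epochs * spec$epoch_length_s
  for (s in seq_len(spec$n_subjects)) {
    theta <- NULL
    for (try in seq_len(spec$max_redraws + 1)) {
      theta <- theta_init(arch)
      theta[a_names] <- with_substream(
        spec$seed, sprintf("subject:%d:draw:%d", s, try),
        stats::rnorm(length(a_names), 0, spec$between_subject_sd))
      ok <- stability_check(spec$params, arch, theta, "baseline")$pass
      if (ok) {
        for (cond in setdiff(conditions, "baseline")) {
          thc <- apply_condition_effects(theta, arch, spec, cond)
          ok <- ok && stability_check(spec$params, arch, thc, cond)$pass
        }
      }
      if (ok) break
      warning(sprintf("subject %d draw %d unstable; resampling", s, try))
      theta <- NULL
    }
    if (is.null(theta))
      stop(sprintf("no stable parameter draw for subject %d after %d attempts",
                   s, spec$max_redraws + 1))
    dat <- list(theta_true = theta)
    for (cond in conditions) {
      thc <- if (cond == "baseline") theta
             else apply_condition_effects(theta, arch, spec, cond)
      y <- simulate_timecourses(
        spec$params, arch, thc, condition = cond,
        duration_s = duration, sampling_rate_hz = spec$sampling_rate_hz,
        seed = substream_seed(spec$seed, sprintf("noise:%d:%s", s, cond)))
      dat[[cond]] <- epoch_timecourses(y, spec$epoch_length_s)
      attr(dat$theta_true, cond) <- thc
    }
    subjects[[s]] <- dat
  }
  list(subjects = subjects, spec = spec, conditions = conditions)
}

# fold the ground-truth condition effects for `cond` into theta's B entries
apply_condition_effects <- function(theta, arch, spec, cond) {
  eff <- spec$condition_effects[[cond]]
  if (is.null(eff)) return(theta)
  th <- theta
  th[paste0("B:", names(eff))] <- eff
  th
}
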