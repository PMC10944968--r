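#' Specification for a simulated continuous-report session
#'
#' Describes one synthetic subject's session of a multi-item delayed
#' estimation task: on each trial `n_items` locations are drawn from an
#' isoeccentric semicircle in one hemifield, subject to a minimum pairwise
#' separation and an exclusion zone around the vertical meridian, and each
#' item is later reported with mixture-distributed error.
#'
#' @param n_trials number of trials.
#' @param n_items items per trial (default 3).
#' @param kappa,sigma report-noise dispersion: Von Mises concentration or,
#'   alternatively, circular SD in radians (exactly one of the two).
#' @param gamma probability that a report is a uniform random guess.
#' @param beta probability that a report is centred on a non-target.
#' @param hemifield `"left"` or `"right"`.
#' @param min_gap_deg minimum pairwise separation of item locations, degrees
#'   of polar angle (default 15).
#' @param meridian_exclusion_deg exclusion zone around the vertical meridian,
#'   degrees of polar angle (default 10).
#' @param seed root seed for this session.
#' @return an object of class `behavior_sim_spec`.
#' @export
behavior_sim_spec <- function(n_trials, n_items = 3, kappa = NULL,
                              sigma = NULL, gamma = 0.1, beta = 0.15,
                              hemifield = c("right", "left"),
                              min_gap_deg = 15, meridian_exclusion_deg = 10,
                              seed = 1) {
  hemifield <- match.arg(hemifield)
  if (is.null(kappa) == is.null(sigma))
    stop("give exactly one of kappa or sigma")
  if (is.null(kappa)) kappa <- sigma_to_kappa(sigma)
  stopifnot(n_trials >= 1, n_items >= 2, kappa >= 0,
            gamma >= 0, beta >= 0, min_gap_deg > 0,
            meridian_exclusion_deg >= 0)
  if (gamma + beta > 1) stop("gamma + beta must be <= 1")
  # available semicircular range after meridian exclusion
  range_deg <- 180 - 2 * meridian_exclusion_deg
  if (min_gap_deg * (n_items - 1) >= range_deg)
    stop("min_gap too large for the available angular range")
  structure(list(n_trials = n_trials, n_items = n_items, kappa = kappa,
                 sigma = kappa_to_sigma(kappa), gamma = gamma, beta = beta,
                 hemifield = hemifield, min_gap_deg = min_gap_deg,
                 meridian_exclusion_deg = meridian_exclusion_deg,
                 seed = seed),
            class = "behavior_sim_spec")
}

# Sample n_items polar angles (radians) in one hemifield honoring the
# pairwise gap and meridian exclusion, by rejection with a retry cap.
sample_locations <- function(spec, max_tries = 1000) {
  excl <- deg2rad(spec$meridian_exclusion_deg)
  gap <- deg2rad(spec$min_gap_deg)
  # polar angle measured from the horizontal meridian; vertical meridian at
  # +/- pi/2. Right hemifield spans (-pi/2, pi/2), left (pi/2, 3*pi/2).
  lo <- -pi / 2 + excl
  hi <- pi / 2 - excl
  for (i in seq_len(max_tries)) {
    ang <- stats::runif(spec$n_items, lo, hi)
    d <- abs(outer(ang, ang, "-"))
    if (min(d[upper.tri(d)]) >= gap) {
      if (spec$hemifield == "left") ang <- wrap_angle(pi - ang)
      return(ang)
    }
  }
  stop("could not sample item locations satisfying the constraints")
}

#' Simulate mixture-distributed continuous-report behavior
#'
#' For each trial, item locations are drawn under the task's spatial
#' constraints and each item is reported under the three-component error
#' model: with probability `1 - gamma - beta` the report is the target plus
#' Von Mises noise, with probability `gamma` uniform on the circle, and with
#' probability `beta` a uniformly chosen non-target plus the same noise. The
#' true component of every report is stored alongside.
#'
#' @param spec a [behavior_sim_spec()].
#' @return data frame with one row per report: `trial`, `report_index`,
#'   `hemifield`, `target`, `nontarget1..`, `reported`, `true_component`.
#' @export
simulate_behavior <- function(spec) {
  stopifnot(inherits(spec, "behavior_sim_spec"))
  m <- spec$n_items - 1
  with_substream(spec$seed, "behavior", {
    rows <- vector("list", spec$n_trials)
    for (tr in seq_len(spec$n_trials)) {
      items <- sample_locations(spec)
      # report all items in random order (self-paced sequential report)
      order_idx <- sample(spec$n_items)
      trial_rows <- lapply(seq_len(spec$n_items), function(j) {
        tgt_i <- order_idx[j]
        tgt <- items[tgt_i]
        nts <- items[-tgt_i]
        u <- stats::runif(1)
        if (u < spec$gamma) {
          rep_ang <- stats::runif(1, -pi, pi)
          comp <- "guess"
        } else if (u < spec$gamma + spec$beta) {
          centre <- nts[sample.int(m, 1)]
          rep_ang <- wrap_angle(centre + rvonmises(1, spec$kappa))
          comp <- "nontarget"
        } else {
          rep_ang <- wrap_angle(tgt + rvonmises(1, spec$kappa))
          comp <- "target"
        }
        out <- data.frame(trial = tr, report_index = j,
                          hemifield = spec$hemifield, target = tgt)
        for (k in seq_len(m)) out[[paste0("nontarget", k)]] <- nts[k]
        out$reported <- rep_ang
        out$true_component <- comp
        out
      })
      rows[[tr]] <- do.call(rbind, trial_rows)
    }
    do.call(rbind, rows)
  })
}

# Von Mises sampler (Best & Fisher 1979 rejection scheme); mean 0.
rvonmises <- function(n, kappa) {
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  if (kappa < 1e-6) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1
  while (i <= n) {
    u1 <- stats::runif(1); u2 <- stats::runif(1); u3 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u2 > 0 || log(c_ / u2) + 1 - c_ >= 0) {
      out[i] <- sign(u3 - 0.5) * acos(pmin(pmax(f, -1), 1))
      i <- i + 1
    }
  }
  out
}
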