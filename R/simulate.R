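#' Gaussian noise with a prescribed two-sided power spectral density
#'
#' Frequency-domain synthesis: independent complex Gaussian Fourier
#' coefficients are scaled so that the series' two-sided PSD equals
#' `psd_fun(f)` (band-limited to the sampling Nyquist), then inverse
#' transformed. Used to generate the spectrally shaped innovations that
#' drive the stochastic network integration.
#'
#' @param n number of samples.
#' @param dt sampling interval in seconds.
#' @param psd_fun function of frequency (Hz) returning the two-sided PSD;
#'   evaluated for `f > 0` (the DC component is set to zero).
#' @return numeric vector of length `n`.
#' @export
colored_noise <- function(n, dt, psd_fun) {
  f <- seq(0, n - 1) / (n * dt)
  half <- floor(n / 2)
  amp <- numeric(n)
  pos <- 2:(half + 1)
  amp[pos] <- sqrt(pmax(psd_fun(f[pos]), 0) * n / dt)
  z <- complex(real = stats::rnorm(n), imaginary = stats::rnorm(n)) / sqrt(2)
  X <- amp * z
  # enforce Hermitian symmetry so the inverse transform is real
  X[1] <- 0
  if (n %% 2 == 0) X[half + 1] <- sqrt(pmax(psd_fun(f[half + 1]), 0) * n / dt) *
      stats::rnorm(1)
  if (n > 2) X[seq(n, half + 2)] <- Conj(X[seq(2, n - half)])
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Simulate observed node timecourses from the network model
#'
#' Stochastic Euler-Maruyama integration of the conductance-based network,
#' driven by spectrally shaped innovations entering the spiny stellate
#' populations, started at the deterministic fixed point with an initial
#' transient discarded. The observed signal per node is the observation
#' gain times the (demeaned) superficial pyramidal membrane potential plus
#' white observation noise whose flat PSD matches the model's
#' observation-noise parameter.
#'
#' @param params a [microcircuit_params()].
#' @param arch a [network_architecture()].
#' @param theta optional named log-scaling parameter vector.
#' @param condition condition label.
#' @param duration_s observed duration in seconds (after the transient).
#' @param sampling_rate_hz output sampling rate; integration runs on a finer
#'   grid (`oversample` times faster) for accuracy of the explicit scheme.
#' @param seed integer seed (all randomness in this routine derives from it).
#' @param burn_s discarded initial transient in seconds.
#' @param oversample integration steps per output sample.
#' @return matrix `[n_nodes x n_samples]` with attributes `sampling_rate`,
#'   `condition`, `nodes`.
#' @export
simulate_timecourses <- function(params, arch, theta = NULL,
                                 condition = "baseline",
                                 duration_s = 10, sampling_rate_hz = 1000,
                                 seed = 1, burn_s = 1, oversample = 4) {
  model <- build_network_model(params, arch, theta, condition)
  lin <- tryCatch(linearize(model), error = function(e)
    stop(sprintf("unstable or non-convergent system (%s); not simulating",
                 conditionMessage(e)), call. = FALSE))
  if (!lin$stable)
    stop(sprintf("unstable system (spectral abscissa %.3g); not simulating",
                 lin$abscissa))
  n <- model$n_nodes
  dt <- 1 / (sampling_rate_hz * oversample)
  n_burn <- round(burn_s / dt)
  n_keep <- round(duration_s * sampling_rate_hz)
  n_steps <- n_burn + n_keep * oversample
  with_substream(seed, paste0("innovations:", condition), {
    W <- matrix(0, n, n_steps)
    for (i in seq_len(n)) {
      a2 <- model$u_amp[i]^2
      W[i, ] <- colored_noise(n_steps, dt, function(f)
        a2 * (f^(-model$u_exp) + model$u_floor))
    }
    ss_idx <- vapply(seq_len(n), pop_index, integer(1), pop = POP_SS,
                     n_nodes = n)
    V <- integrate_network(model$GE, model$GI, model$C, model$gL,
                           model$VL, model$VE, model$VI,
                           model$kE, model$kI, model$u,
                           model$slope, model$thresh,
                           lin$x_star, W, ss_idx - 1L,
                           dt, n_burn, oversample)
    sp_idx <- vapply(seq_len(n), pop_index, integer(1), pop = POP_SP,
                     n_nodes = n)
    y <- V[sp_idx, , drop = FALSE] - lin$x_star[sp_idx]
    y <- y * model$obs_gain
    dt_obs <- 1 / sampling_rate_hz
    obs_sd <- sqrt(model$obs_psd / dt_obs)
    y <- y + matrix(stats::rnorm(length(y)), nrow(y)) * obs_sd
    structure(y, sampling_rate = sampling_rate_hz, condition = condition,
              nodes = arch$nodes)
  })
}
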