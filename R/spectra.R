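#' Analysis windows relative to stimulus onset
#'
#' The three canonical 800 ms windows: baseline (-900 to -100 ms), early
#' delay (400 to 1200 ms) and late delay (1200 to 2000 ms). All three keep
#' at least 100 ms clear of the stimulus interval (0-200 ms) and the report
#' interval (from 2200 ms).
#'
#' @param label one of `"baseline"`, `"early_delay"`, `"late_delay"`.
#' @param start_ms,end_ms window bounds for a custom window.
#' @return an `epoch_window` list with `label`, `start_ms`, `end_ms`.
#' @export
epoch_window <- function(label, start_ms = NULL, end_ms = NULL) {
  canonical <- list(baseline = c(-900, -100),
                    early_delay = c(400, 1200),
                    late_delay = c(1200, 2000))
  if (is.null(start_ms)) {
    if (!label %in% names(canonical)) stop("unknown canonical window: ", label)
    start_ms <- canonical[[label]][1]
    end_ms <- canonical[[label]][2]
  }
  stopifnot(end_ms > start_ms)
  structure(list(label = label, start_ms = start_ms, end_ms = end_ms),
            class = "epoch_window")
}

#' @rdname epoch_window
#' @export
canonical_windows <- function() {
  lapply(c("baseline", "early_delay", "late_delay"), epoch_window)
}

#' Discrete prolate spheroidal sequence (Slepian) tapers
#'
#' Computed as the leading eigenvectors of the standard symmetric
#' tridiagonal matrix whose eigenvectors are the DPSS, normalized to unit
#' energy with a positive-mean sign convention.
#'
#' @param n taper length in samples.
#' @param nw time-half-bandwidth product `N*W` (W in cycles per sample).
#' @param k number of tapers (default `max(1, floor(2*nw) - 1)`).
#' @return matrix `n x k`, one taper per column.
#' @export
dpss_tapers <- function(n, nw, k = max(1L, floor(2 * nw) - 1L)) {
  stopifnot(n >= 2, nw > 0, k >= 1, k <= n)
  w <- nw / n
  t <- 0:(n - 1)
  diag_main <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  diag_off <- t[-1] * (n - t[-1]) / 2
  T <- diag(diag_main)
  T[cbind(2:n, 1:(n - 1))] <- diag_off
  T[cbind(1:(n - 1), 2:n)] <- diag_off
  e <- eigen(T, symmetric = TRUE)
  h <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    h[, j] <- h[, j] / sqrt(sum(h[, j]^2))
    if (sum(h[, j]) < 0) h[, j] <- -h[, j]
  }
  h
}

# slice an [nodes x samples x epochs] array to a window, given the epoch
# time axis start (ms) and sampling rate
slice_window <- function(x, window, sampling_rate, t0_ms) {
  i0 <- round((window$start_ms - t0_ms) / 1000 * sampling_rate) + 1
  i1 <- round((window$end_ms - t0_ms) / 1000 * sampling_rate)
  if (i0 < 1 || i1 > dim(x)[2])
    stop("window falls outside the epoch time axis")
  x[, i0:i1, , drop = FALSE]
}

#' Multitaper cross-spectral density estimate
#'
#' DPSS-tapered cross-spectra are computed per epoch (after per-epoch,
#' per-channel demeaning), averaged over tapers and epochs, and linearly
#' interpolated from the Fourier grid onto the requested analysis grid.
#' The estimate is Hermitian by construction and scaled as a two-sided
#' power spectral density (units^2 per Hz), matching [predicted_csd()].
#'
#' @param x numeric array `[n_channels, n_samples, n_epochs]` (a matrix is
#'   treated as one epoch), or the output of [simulate_timecourses()] after
#'   [epoch_timecourses()].
#' @param grid a [frequency_grid()].
#' @param sampling_rate sampling rate in Hz (defaults to the
#'   `sampling_rate` attribute of `x`).
#' @param window optional [epoch_window()] to slice out of each epoch;
#'   requires `t0_ms`.
#' @param t0_ms time of the first sample of each epoch relative to stimulus
#'   onset, in ms (only used with `window`).
#' @param half_bandwidth_hz multitaper smoothing half-bandwidth (default
#'   2 Hz).
#' @param detrend remove a per-epoch linear trend as well as the mean.
#' @return a [cross_spectrum()].
#' @export
estimate_csd <- function(x, grid = frequency_grid(), sampling_rate = NULL,
                         window = NULL, t0_ms = NULL,
                         half_bandwidth_hz = 2, detrend = FALSE) {
  sampling_rate <- sampling_rate %||% attr(x, "sampling_rate")
  if (is.null(sampling_rate)) stop("sampling_rate is required")
  if (length(dim(x)) == 2) x <- array(x, c(dim(x), 1))
  if (!is.null(window)) {
    if (is.null(t0_ms)) stop("window slicing requires t0_ms")
    x <- slice_window(x, window, sampling_rate, t0_ms)
  }
  n_ch <- dim(x)[1]; n_s <- dim(x)[2]; n_ep <- dim(x)[3]
  if (grid$f_max > sampling_rate / 2)
    stop("analysis grid exceeds the Nyquist frequency")
  dt <- 1 / sampling_rate
  if (n_s * dt < 1 / grid$f_min)
    stop(sprintf(
      "epoch too short for %g Hz resolution: need at least %.3f s (%d samples)",
      grid$f_min, 1 / grid$f_min, ceiling(sampling_rate / grid$f_min)))
  nw <- n_s * dt * half_bandwidth_hz
  tapers <- dpss_tapers(n_s, nw)
  k <- ncol(tapers)
  fbins <- seq(0, n_s - 1) / (n_s * dt)
  keep <- fbins <= sampling_rate / 2
  nf <- sum(keep)
  Sacc <- array(0i, c(n_ch, n_ch, nf))
  tt <- seq_len(n_s)
  for (ep in seq_len(n_ep)) {
    xe <- x[, , ep, drop = TRUE]
    if (n_ch == 1) xe <- matrix(xe, nrow = 1)
    xe <- xe - rowMeans(xe)
    if (detrend) {
      for (ch in seq_len(n_ch))
        xe[ch, ] <- stats::residuals(stats::lm.fit(cbind(1, tt),
                                                   xe[ch, ]))
    }
    for (j in seq_len(k)) {
      X <- t(stats::mvfft(t(xe * rep(tapers[, j], each = n_ch))))[, keep,
                                                                  drop = FALSE]
      if (n_ch == 1) X <- matrix(X, nrow = 1)
      for (a in seq_len(n_ch)) for (b in a:n_ch) {
        cs <- X[a, ] * Conj(X[b, ])
        Sacc[a, b, ] <- Sacc[a, b, ] + cs
        if (b > a) Sacc[b, a, ] <- Sacc[b, a, ] + Conj(cs)
      }
    }
  }
  Sacc <- Sacc * dt / (k * n_ep)
  # interpolate real and imaginary parts onto the analysis grid
  out <- array(0i, c(n_ch, n_ch, length(grid$freqs)))
  for (i in seq_len(n_ch)) for (j in seq_len(n_ch)) {
    re <- stats::approx(fbins[keep], Re(Sacc[i, j, ]), xout = grid$freqs,
                        rule = 2)$y
    im <- stats::approx(fbins[keep], Im(Sacc[i, j, ]), xout = grid$freqs,
                        rule = 2)$y
    out[i, j, ] <- complex(real = re, imaginary = im)
  }
  for (f in seq_along(grid$freqs)) {
    Sk <- out[, , f]
    Sk <- (Sk + Conj(t(Sk))) / 2
    diag(Sk) <- Re(diag(Sk))
    out[, , f] <- Sk
  }
  cross_spectrum(out, grid$freqs,
                 nodes = attr(x, "nodes"),
                 condition = attr(x, "condition"),
                 window = if (is.null(window)) NA else window$label,
                 n_epochs = n_ep)
}

#' Chop a continuous multichannel timecourse into equal epochs
#'
#' @param y matrix `[n_channels x n_samples]` with a `sampling_rate`
#'   attribute (e.g. from [simulate_timecourses()]).
#' @param epoch_length_s epoch length in seconds.
#' @return array `[n_channels, samples_per_epoch, n_epochs]` carrying the
#'   input's attributes.
#' @export
epoch_timecourses <- function(y, epoch_length_s) {
  sr <- attr(y, "sampling_rate")
  if (is.null(sr)) stop("y must carry a sampling_rate attribute")
  spe <- round(epoch_length_s * sr)
  n_ep <- floor(ncol(y) / spe)
  if (n_ep < 1) stop("timecourse shorter than one epoch")
  out <- array(y[, seq_len(spe * n_ep)], c(nrow(y), spe, n_ep))
  attr(out, "sampling_rate") <- sr
  attr(out, "condition") <- attr(y, "condition")
  attr(out, "nodes") <- attr(y, "nodes")
  out
}
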