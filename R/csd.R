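#' Frequency grid for spectral analysis
#'
#' @param f_min,f_max band edges in Hz (defaults 2 and 100).
#' @param step grid step in Hz (default 1).
#' @return object of class `frequency_grid` with a `freqs` vector.
#' @export
frequency_grid <- function(f_min = 2, f_max = 100, step = 1) {
  stopifnot(f_min > 0, f_max > f_min, step > 0)
  structure(list(f_min = f_min, f_max = f_max, step = step,
                 freqs = seq(f_min, f_max, by = step)),
            class = "frequency_grid")
}

# two-sided innovations power spectral density per node at frequencies f:
# amplitude^2 * (f^-exponent + white floor), the conventional mixture of a
# power law and a flat component.
innovations_psd <- function(model, f) {
  outer(model$u_amp^2, f^(-model$u_exp) + model$u_floor)
}

#' Analytic cross-spectral density predicted by the linearized network
#'
#' For the linearization `dx = J x dt + D dw`, `y = L x + e`, the predicted
#' cross-spectrum at frequency `f` is
#' `S(f) = M(f) diag(G_u(f)) M(f)* + S_obs`, with transfer function
#' `M(f) = L (2*pi*i*f*I - J)^-1 D`, `G_u` the parameterized innovations
#' spectrum and `S_obs` the flat observation-noise spectrum. The result is
#' Hermitian positive semidefinite at every frequency by construction.
#'
#' @param params a [microcircuit_params()].
#' @param arch a [network_architecture()].
#' @param theta optional named log-scaling parameter vector.
#' @param condition condition label (`"baseline"` leaves B inactive).
#' @param grid a [frequency_grid()].
#' @return a `cross_spectrum` object: complex array
#'   `[n_nodes, n_nodes, n_freq]` with attributes `freqs`, `nodes`,
#'   `condition`.
#' @export
predicted_csd <- function(params, arch, theta = NULL,
                          condition = "baseline", grid = frequency_grid()) {
  model <- build_network_model(params, arch, theta, condition)
  lin <- linearize(model)
  if (!lin$stable)
    stop(sprintf("unstable linearization (spectral abscissa %.3g >= 0)",
                 lin$abscissa))
  f <- grid$freqs
  n <- model$n_nodes
  nf <- length(f)
  gu <- innovations_psd(model, f)   # n x nf
  S <- array(0i, c(n, n, nf))
  I <- diag(nrow(lin$J))
  for (k in seq_len(nf)) {
    M <- lin$L %*% solve(2i * pi * f[k] * I - lin$J, lin$D)  # n x n
    Sk <- M %*% (gu[, k] * Conj(t(M)))
    Sk <- (Sk + Conj(t(Sk))) / 2
    diag(Sk) <- Re(diag(Sk)) + model$obs_psd
    S[, , k] <- Sk
  }
  cross_spectrum(S, f, nodes = arch$nodes, condition = condition)
}

#' Construct a cross-spectrum object
#'
#' @param S complex array `[n, n, n_freq]`, Hermitian in its first two
#'   dimensions at every frequency.
#' @param freqs frequency vector (Hz).
#' @param nodes channel labels.
#' @param condition,window,n_epochs metadata.
#' @return object of class `cross_spectrum`.
#' @export
cross_spectrum <- function(S, freqs, nodes = NULL, condition = NA,
                           window = NA, n_epochs = NA) {
  stopifnot(length(dim(S)) == 3, dim(S)[1] == dim(S)[2],
            dim(S)[3] == length(freqs))
  structure(S, freqs = freqs, nodes = nodes, condition = condition,
            window = window, n_epochs = n_epochs,
            class = "cross_spectrum")
}

#' @export
print.cross_spectrum <- function(x, ...) {
  d <- dim(x)
  f <- attr(x, "freqs")
  cat(sprintf("cross_spectrum: %d channels, %d frequencies (%g-%g Hz)\n",
              d[1], d[3], min(f), max(f)))
  invisible(x)
}

#' Hermitian and positive-semidefiniteness diagnostics of a cross-spectrum
#'
#' @param cs a `cross_spectrum`.
#' @param tol tolerance on the Hermitian asymmetry and on negative
#'   eigenvalues (relative to the largest eigenvalue).
#' @return list with `hermitian` and `psd` logicals and worst-case measures.
#' @export
check_csd <- function(cs, tol = 1e-8) {
  nf <- dim(cs)[3]
  worst_asym <- 0
  worst_neg <- 0
  for (k in seq_len(nf)) {
    Sk <- cs[, , k]
    asym <- max(abs(Sk - Conj(t(Sk))))
    ev <- eigen((Sk + Conj(t(Sk))) / 2, only.values = TRUE,
                symmetric = TRUE)$values
    worst_asym <- max(worst_asym, asym)
    worst_neg <- max(worst_neg, -min(ev) / max(abs(ev)))
  }
  list(hermitian = worst_asym < tol, psd = worst_neg < tol,
       worst_asymmetry = worst_asym, worst_negative_fraction = worst_neg)
}

#' Magnitude-squared coherence of a cross-spectrum
#'
#' @param cs a `cross_spectrum` with strictly positive diagonal.
#' @return real array `[n, n, n_freq]` with values in `[0, 1]` and unit
#'   diagonal.
#' @export
coherence <- function(cs) {
  n <- dim(cs)[1]
  nf <- dim(cs)[3]
  out <- array(0, dim(cs))
  for (k in seq_len(nf)) {
    d <- Re(diag(cs[, , k]))
    if (any(d <= 0)) stop("zero or negative diagonal in cross-spectrum")
    out[, , k] <- Mod(cs[, , k])^2 / outer(d, d)
  }
  out
}
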