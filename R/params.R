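#' Default microcircuit parameters for a network architecture
#'
#' Each node is a four-population conductance-based microcircuit (spiny
#' stellate, superficial pyramidal, inhibitory interneuron, deep pyramidal).
#' Population dynamics follow the Morris-Lecar form: the membrane potential
#' integrates leak, AMPA-mediated excitatory and GABA-A-mediated inhibitory
#' currents, `C dV/dt = sum_k g_k (V_k - V) + u`, while each conductance
#' relaxes at its channel rate constant toward a target set by presynaptic
#' firing rates (a logistic function of presynaptic membrane potential).
#'
#' The numerical constants below are the package's defaults, chosen once so
#' that the default network has a stable fixed point and rich spectral
#' content across the 2-100 Hz analysis band. Units: potentials in mV,
#' conductances relative to the leak conductance, rate constants in 1/s,
#' capacitance in units of leak-conductance x seconds (so `C/gL` is the
#' membrane time constant in seconds).
#'
#' @param arch a [network_architecture()].
#' @return an object of class `microcircuit_params`: a list with components
#'   `pop` (population constants), `intrinsic` (within-node coupling),
#'   `extrinsic` (per-edge coupling strengths), `noise` (innovations and
#'   observation-noise spectral parameters) and `obs` (observation gains).
#' @export
microcircuit_params <- function(arch) {
  n <- length(arch$nodes)
  pop <- list(
    # spiny stellate, superficial pyramidal, inhibitory interneuron, deep pyramidal
    C = rep(1 / 128, 4),          # membrane time constant ~7.8 ms
    gL = rep(1, 4),
    VL = -70, VE = 60, VI = -90,  # reversal potentials (mV)
    kE = 250, kI = 62.5,          # AMPA / GABA-A rate constants (1/s)
    u = c(2.0, 1.5, 1.5, 1.5),    # background drive current per population
    slope = 1 / 8,                # firing-rate sigmoid slope (1/mV)
    thresh = -48)                 # sigmoid inflection (mV)
  intrinsic <- list(
    # excitatory (AMPA) within-node couplings, per unit presynaptic rate
    ss_to_sp = 0.8, sp_to_ss = 0.4, sp_to_dp = 0.8,
    ss_to_ii = 0.4, sp_to_ii = 0.4, dp_to_ii = 0.4,
    ii_to_ss = 0.8, ii_to_sp = 0.8, ii_to_dp = 0.8,  # GABA-A projections
    self = c(0.6, 0.6, 0.6, 0.6))                    # inhibitory self-gain
  extrinsic <- list(ff = 0.1, fb = 0.1, lateral = 0.1)
  noise <- list(
    u_amp = rep(0.25, n),   # innovations amplitude per node (current units)
    u_exp = 1,              # innovations spectral exponent (1/f by default)
    u_floor = 0.5,          # white floor mixed into the innovations spectrum
    obs_psd = rep(1e-4, n)) # flat observation-noise PSD (signal units^2 / Hz)
  obs <- list(gain = rep(1, n))
  structure(list(n_nodes = n, pop = pop, intrinsic = intrinsic,
                 extrinsic = extrinsic, noise = noise, obs = obs),
            class = "microcircuit_params")
}

#' @export
print.microcircuit_params <- function(x, ...) {
  cat(sprintf("microcircuit_params for %d node(s); tau_m = %.1f ms, kE = %g/s, kI = %g/s\n",
              x$n_nodes, 1000 * x$pop$C[1] / x$pop$gL[1], x$pop$kE, x$pop$kI))
  invisible(x)
}

# Names of the estimable log-scaling parameter vector for an architecture:
# per-edge extrinsic scalings (A), per-modulated-edge condition scalings (B),
# per-node intrinsic self-gain, innovations amplitude and observation gain.
theta_names <- function(arch) {
  el <- edge_labels(arch)
  c(paste0("A:", el),
    paste0("B:", el[arch$edges$b_mask]),
    paste0("g:", arch$nodes),
    paste0("u:", arch$nodes),
    paste0("obs:", arch$nodes))
}

#' Zero log-scaling parameter vector
#'
#' All connectivity, gain and noise parameters are estimated as log-scaling
#' deviations from the defaults in [microcircuit_params()]; the zero vector
#' is therefore the prior mean and leaves the defaults untouched.
#'
#' @param arch a [network_architecture()].
#' @return named numeric vector of zeros.
#' @export
theta_init <- function(arch) {
  nm <- theta_names(arch)
  stats::setNames(numeric(length(nm)), nm)
}

# Apply a log-scaling parameter vector to default params, returning the
# effective per-edge strengths and scaled node-level quantities.
# condition = "baseline" ignores B; any other label applies exp(B) on the
# b_mask edges.
effective_params <- function(params, arch, theta = NULL,
                             condition = "baseline") {
  n <- params$n_nodes
  ne <- n_edges(arch)
  th <- theta_init(arch)
  if (!is.null(theta)) {
    stopifnot(all(names(theta) %in% names(th)))
    th[names(theta)] <- theta
  }
  type_base <- c(feedforward = params$extrinsic$ff,
                 feedback = params$extrinsic$fb,
                 lateral = params$extrinsic$lateral)
  strength <- unname(type_base[arch$edges$type]) *
    exp(th[seq_len(ne)])
  if (condition != "baseline") {
    b <- numeric(ne)
    b[arch$edges$b_mask] <- th[grep("^B:", names(th))]
    strength <- strength * exp(b)
  }
  list(strength = strength,
       self_scale = exp(th[grep("^g:", names(th))]),
       u_amp = params$noise$u_amp * exp(th[grep("^u:", names(th))]),
       obs_gain = params$obs$gain * exp(th[grep("^obs:", names(th))]))
}
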