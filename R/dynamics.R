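# Population indices within a node: spiny stellate, superficial pyramidal,
# inhibitory interneuron, deep pyramidal.
POP_SS <- 1L
POP_SP <- 2L
POP_II <- 3L
POP_DP <- 4L

pop_index <- function(node, pop, n_nodes) (node - 1L) * 4L + pop

#' Build the compiled network model for one condition
#'
#' Assembles the excitatory (AMPA) and inhibitory (GABA-A) conductance-target
#' coupling matrices over all populations of all nodes, combining the
#' within-node microcircuit rules with the laminar extrinsic rules:
#' feedforward edges project from the source's superficial pyramidal cells to
#' the target's spiny stellate cells; feedback edges from the source's deep
#' pyramidal cells to the target's inhibitory interneurons and superficial
#' pyramidal cells; lateral edges carry both sets of projections at half
#' weight each. Condition modulation multiplies modulated edge strengths by
#' `exp(B)`.
#'
#' @param params a [microcircuit_params()].
#' @param arch a [network_architecture()].
#' @param theta named log-scaling parameter vector (see [theta_init()]);
#'   `NULL` for the defaults.
#' @param condition `"baseline"` (B inactive) or any other condition label
#'   (B active on the `b_mask` edges).
#' @return a `network_model` list with coupling matrices `GE`, `GI`
#'   (`4n x 4n`), population constant vectors expanded over nodes, the
#'   effective innovations amplitudes and observation gains, and index
#'   bookkeeping.
#' @export
build_network_model <- function(params, arch, theta = NULL,
                                condition = "baseline") {
  n <- params$n_nodes
  stopifnot(length(arch$nodes) == n)
  np <- 4L * n
  eff <- effective_params(params, arch, theta, condition)
  ir <- params$intrinsic

  GE <- matrix(0, np, np)
  GI <- matrix(0, np, np)
  for (i in seq_len(n)) {
    ss <- pop_index(i, POP_SS, n); sp <- pop_index(i, POP_SP, n)
    ii <- pop_index(i, POP_II, n); dp <- pop_index(i, POP_DP, n)
    sc <- eff$self_scale[i]
    GE[sp, ss] <- ir$ss_to_sp
    GE[ss, sp] <- ir$sp_to_ss
    GE[dp, sp] <- ir$sp_to_dp
    GE[ii, ss] <- ir$ss_to_ii
    GE[ii, sp] <- ir$sp_to_ii
    GE[ii, dp] <- ir$dp_to_ii
    GI[ss, ii] <- ir$ii_to_ss
    GI[sp, ii] <- ir$ii_to_sp
    GI[dp, ii] <- ir$ii_to_dp
    idx <- c(ss, sp, ii, dp)
    GI[cbind(idx, idx)] <- GI[cbind(idx, idx)] + ir$self * sc
  }
  node_of <- match(arch$edges$from, arch$nodes)
  node_to <- match(arch$edges$to, arch$nodes)
  for (e in seq_len(n_edges(arch))) {
    s <- eff$strength[e]
    a <- node_of[e]; b <- node_to[e]
    ff_part <- switch(arch$edges$type[e],
                      feedforward = 1, feedback = 0, lateral = 0.5)
    fb_part <- switch(arch$edges$type[e],
                      feedforward = 0, feedback = 1, lateral = 0.5)
    if (ff_part > 0)
      GE[pop_index(b, POP_SS, n), pop_index(a, POP_SP, n)] <-
        GE[pop_index(b, POP_SS, n), pop_index(a, POP_SP, n)] + s * ff_part
    if (fb_part > 0) {
      GE[pop_index(b, POP_II, n), pop_index(a, POP_DP, n)] <-
        GE[pop_index(b, POP_II, n), pop_index(a, POP_DP, n)] + s * fb_part
      GE[pop_index(b, POP_SP, n), pop_index(a, POP_DP, n)] <-
        GE[pop_index(b, POP_SP, n), pop_index(a, POP_DP, n)] + s * fb_part
    }
  }
  structure(list(
    n_nodes = n, n_pop = np, n_states = 3L * np,
    GE = GE, GI = GI,
    C = rep(params$pop$C, n), gL = rep(params$pop$gL, n),
    VL = params$pop$VL, VE = params$pop$VE, VI = params$pop$VI,
    kE = params$pop$kE, kI = params$pop$kI,
    u = rep(params$pop$u, n),
    slope = params$pop$slope, thresh = params$pop$thresh,
    u_amp = eff$u_amp, u_exp = params$noise$u_exp,
    u_floor = params$noise$u_floor,
    obs_psd = params$noise$obs_psd, obs_gain = eff$obs_gain,
    condition = condition), class = "network_model")
}

# firing-rate nonlinearity and its derivative
sigmoid_rate <- function(V, model) {
  1 / (1 + exp(-model$slope * (V - model$thresh)))
}
sigmoid_rate_deriv <- function(V, model) {
  s <- sigmoid_rate(V, model)
  model$slope * s * (1 - s)
}

#' Deterministic right-hand side of the network dynamics
#'
#' State layout: `x = c(V, gE, gI)`, each block of length `4 * n_nodes` in
#' population-major order within node. The membrane equation is the
#' Morris-Lecar current balance; each conductance relaxes at its channel
#' rate constant toward the coupling-weighted presynaptic firing rate.
#'
#' @param x state vector (finite).
#' @param model a `network_model` from [build_network_model()].
#' @param u_extra optional additional current input per population (length
#'   `4 * n_nodes`), e.g. innovations during stochastic integration.
#' @return `dx/dt`, same length as `x`.
#' @export
network_rhs <- function(x, model, u_extra = NULL) {
  if (!all(is.finite(x))) stop("non-finite state passed to network_rhs")
  np <- model$n_pop
  V <- x[1:np]
  gE <- x[np + 1:np]
  gI <- x[2 * np + 1:np]
  drive <- model$u
  if (!is.null(u_extra)) drive <- drive + u_extra
  rate <- sigmoid_rate(V, model)
  dV <- (model$gL * (model$VL - V) + gE * (model$VE - V) +
           gI * (model$VI - V) + drive) / model$C
  dgE <- model$kE * (drop(model$GE %*% rate) - gE)
  dgI <- model$kI * (drop(model$GI %*% rate) - gI)
  c(dV, dgE, dgI)
}

# Analytic Jacobian of network_rhs at state x (12n x 12n). Verified against
# central finite differences in the test suite.
network_jacobian <- function(x, model) {
  np <- model$n_pop
  V <- x[1:np]
  gE <- x[np + 1:np]
  gI <- x[2 * np + 1:np]
  dr <- sigmoid_rate_deriv(V, model)
  J <- matrix(0, 3 * np, 3 * np)
  iV <- 1:np; iE <- np + 1:np; iI <- 2 * np + 1:np
  # dV'/dV, dV'/dgE, dV'/dgI
  J[cbind(iV, iV)] <- -(model$gL + gE + gI) / model$C
  J[cbind(iV, iE)] <- (model$VE - V) / model$C
  J[cbind(iV, iI)] <- (model$VI - V) / model$C
  # dgE'/dV = kE * GE * diag(rate'), dgE'/dgE = -kE
  J[iE, iV] <- model$kE * sweep(model$GE, 2, dr, "*")
  J[cbind(iE, iE)] <- -model$kE
  J[iI, iV] <- model$kI * sweep(model$GI, 2, dr, "*")
  J[cbind(iI, iI)] <- -model$kI
  J
}

# Resting-state initialization: leak equilibrium with zero conductances.
resting_state <- function(model) {
  np <- model$n_pop
  V0 <- model$VL + model$u / model$gL
  r0 <- sigmoid_rate(V0, model)
  c(V0, drop(model$GE %*% r0), drop(model$GI %*% r0))
}

#' Fixed point of the deterministic network dynamics
#'
#' Damped Newton iteration from the resting-state initialization, using the
#' analytic Jacobian. Converges in a handful of iterations for parameter
#' sets anywhere near the defaults.
#'
#' @param model a `network_model`.
#' @param tol infinity-norm tolerance on the residual.
#' @param max_iter maximum Newton iterations.
#' @return list with `x` (fixed point), `residual`, `n_iter`.
#' @export
fixed_point <- function(model, tol = 1e-9, max_iter = 100) {
  x <- resting_state(model)
  for (it in seq_len(max_iter)) {
    f <- network_rhs(x, model)
    if (max(abs(f)) < tol)
      return(list(x = x, residual = max(abs(f)), n_iter = it - 1L))
    J <- network_jacobian(x, model)
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) stop("singular Jacobian in fixed-point search")
    lambda <- 1
    f0 <- sum(f^2)
    repeat {
      x_new <- x + lambda * step
      f_new <- tryCatch(network_rhs(x_new, model), error = function(e) NULL)
      if (!is.null(f_new) && all(is.finite(f_new)) && sum(f_new^2) < f0) break
      lambda <- lambda / 2
      if (lambda < 1e-8) {
        nodes <- which_node_max_residual(f, model)
        stop(sprintf("fixed-point search stalled (worst residual at node %s)",
                     nodes))
      }
    }
    x <- x_new
  }
  f <- network_rhs(x, model)
  if (max(abs(f)) >= tol)
    stop(sprintf("fixed point did not converge (worst residual at node %s)",
                 which_node_max_residual(f, model)))
  list(x = x, residual = max(abs(f)), n_iter = max_iter)
}

which_node_max_residual <- function(f, model) {
  np <- model$n_pop
  idx <- which.max(abs(f))
  pop_global <- ((idx - 1L) %% np) + 1L
  ceiling(pop_global / 4)
}

#' Linearize the network around its fixed point
#'
#' Returns the state Jacobian at the fixed point together with the input
#' matrix routing per-node innovations (currents on the spiny stellate
#' population) into the state equations and the output matrix mapping states
#' to the observed per-node signal (observation gain times the superficial
#' pyramidal membrane potential).
#'
#' @param model a `network_model`.
#' @return list with `x_star`, `J` (state Jacobian), `D` (input matrix,
#'   states x nodes), `L` (output matrix, nodes x states), `stable`
#'   (logical) and `abscissa` (max real part of the eigenvalues).
#' @export
linearize <- function(model) {
  fp <- fixed_point(model)
  J <- network_jacobian(fp$x, model)
  np <- model$n_pop
  n <- model$n_nodes
  D <- matrix(0, 3 * np, n)
  L <- matrix(0, n, 3 * np)
  for (i in seq_len(n)) {
    ss <- pop_index(i, POP_SS, n)
    sp <- pop_index(i, POP_SP, n)
    D[ss, i] <- 1 / model$C[ss]      # innovation current enters dV_ss
    L[i, sp] <- model$obs_gain[i]    # observed signal: sp membrane potential
  }
  ev <- eigen(J, only.values = TRUE)$values
  kappa_cond <- kappa(J, exact = FALSE)
  if (kappa_cond > 1e12)
    warning("linearized system is ill-conditioned (kappa > 1e12)")
  abscissa <- max(Re(ev))
  list(x_star = fp$x, J = J, D = D, L = L,
       stable = abscissa < 0, abscissa = abscissa)
}

#' Stability check of a parameterized network
#'
#' @param params a [microcircuit_params()].
#' @param arch a [network_architecture()].
#' @param theta optional log-scaling parameter vector.
#' @param condition condition label.
#' @return list with `pass` (all Jacobian eigenvalues in the open left half
#'   plane) and `abscissa` (the spectral abscissa).
#' @export
stability_check <- function(params, arch, theta = NULL,
                            condition = "baseline") {
  model <- build_network_model(params, arch, theta, condition)
  lin <- tryCatch(linearize(model), error = function(e) NULL)
  if (is.null(lin)) return(list(pass = FALSE, abscissa = Inf))
  list(pass = lin$stable, abscissa = lin$abscissa)
}
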