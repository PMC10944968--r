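test_that("membrane equation reduces to its algebraic limits", {
  arch <- fix_arch3()
  model <- build_network_model(fix_params3(), arch)
  np <- model$n_pop
  # zero conductances, zero drive: V' = gL*(VL - V)/C vanishes at V = VL
  m0 <- model
  m0$u <- rep(0, np)
  x <- c(rep(m0$VL, np), rep(0, 2 * np))
  dx <- network_rhs(x, m0)
  expect_equal(dx[1:np], rep(0, np), tolerance = 1e-12)
  # leak-only equilibrium shifts linearly with the drive
  x2 <- c(m0$VL + model$u / model$gL, rep(0, 2 * np))
  dx2 <- network_rhs(x2, model)
  expect_equal(dx2[1:np], rep(0, np), tolerance = 1e-10)
  expect_error(network_rhs(c(NaN, x[-1]), model), "finite")
})

test_that("membrane relaxation matches the closed-form linear solution", {
  skip_if_not_installed("deSolve")
  arch <- fix_arch3()
  model <- build_network_model(fix_params3(), arch)
  np <- model$n_pop
  gE0 <- rep(0.3, np); gI0 <- rep(0.2, np)
  # with frozen conductances the V equation is scalar linear per population
  rhsV <- function(t, V, parms) {
    x <- c(V, gE0, gI0)
    list(network_rhs(x, model)[1:np])
  }
  V0 <- rep(-70, np)
  sol <- deSolve::ode(V0, seq(0, 0.05, by = 0.005), rhsV, NULL,
                      method = "ode45", rtol = 1e-10, atol = 1e-12)
  gtot <- model$gL + gE0 + gI0
  Veq <- (model$gL * model$VL + gE0 * model$VE + gI0 * model$VI + model$u) /
    gtot
  for (row in c(3, 7, 11)) {
    t <- sol[row, 1]
    Vexp <- Veq + (V0 - Veq) * exp(-gtot * t / model$C)
    expect_equal(unname(sol[row, -1]), unname(Vexp), tolerance = 1e-6)
  }
})

test_that("fixed point converges, decouples, and moves continuously", {
  arch <- fix_arch3()
  params <- fix_params3()
  model <- build_network_model(params, arch)
  fp <- fixed_point(model)
  expect_lt(fp$residual, 1e-9)
  # uncoupled network: fixed point equals independently computed 1-node one
  th0 <- theta_init(arch)
  th0[grep("^A:", names(th0))] <- -40
  m_unc <- build_network_model(params, arch, th0)
  fp_unc <- fixed_point(m_unc)
  arch1 <- network_architecture("node1", 1,
                                data.frame(from = character(),
                                           to = character(),
                                           type = character()),
                                logical(0))
  fp1 <- fixed_point(build_network_model(microcircuit_params(arch1), arch1))
  # node-1 sub-state of the uncoupled 3-node system
  idx <- c(1:4, 13:16, 25:28)
  expect_equal(fp_unc$x[idx], fp1$x, tolerance = 1e-7)
  # continuity under a tiny extrinsic perturbation
  th_eps <- theta_init(arch)
  th_eps[1] <- 1e-6
  fp_eps <- fixed_point(build_network_model(params, arch, th_eps))
  expect_lt(max(abs(fp_eps$x - fp$x)), 1e-3)
})

test_that("analytic Jacobian matches central finite differences", {
  arch <- fix_arch3()
  model <- build_network_model(fix_params3(), arch)
  x <- fixed_point(model)$x
  J <- wmdcm:::network_jacobian(x, model)
  h <- 1e-5
  Jfd <- matrix(0, length(x), length(x))
  for (j in seq_along(x)) {
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    Jfd[, j] <- (network_rhs(xp, model) - network_rhs(xm, model)) / (2 * h)
  }
  expect_lt(max(abs(J - Jfd)) / max(abs(J)), 1e-6)
})

test_that("linearization is stable at defaults and block-diagonal when uncoupled", {
  arch <- fix_arch3()
  params <- fix_params3()
  lin <- linearize(build_network_model(params, arch))
  expect_true(lin$stable)
  expect_lt(lin$abscissa, 0)
  th0 <- theta_init(arch)
  th0[grep("^A:", names(th0))] <- -40
  lin0 <- linearize(build_network_model(params, arch, th0))
  # cross-node blocks of the uncoupled Jacobian vanish
  node_of_state <- rep(ceiling(seq_len(12) / 4), 3)
  for (a in 1:3) for (b in 1:3) {
    if (a == b) next
    blk <- lin0$J[node_of_state == a, node_of_state == b]
    expect_lt(max(abs(blk)), 1e-12)
  }
})

test_that("stability check fails under grossly amplified excitation and varies continuously", {
  arch <- fix_arch3()
  params <- fix_params3()
  expect_true(stability_check(params, arch)$pass)
  th <- theta_init(arch)
  th[grep("^A:", names(th))] <- log(100)
  expect_false(stability_check(params, arch, th)$pass)
  # spectral abscissa is continuous along one coupling parameter
  sweep_vals <- seq(0, 0.5, length.out = 6)
  absc <- vapply(sweep_vals, function(v) {
    th <- theta_init(arch); th[1] <- v
    stability_check(params, arch, th)$abscissa
  }, numeric(1))
  expect_true(all(abs(diff(absc)) < 10))
  expect_true(all(is.finite(absc)))
})
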