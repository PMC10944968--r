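test_that("fit metrics behave on constructed spectra", {
  arch <- fix_arch3()
  S <- predicted_csd(fix_params3(), arch, grid = frequency_grid(2, 60, 2))
  m <- fit_metrics(S, S)
  expect_equal(m$r_modulus, 1)
  expect_equal(m$r_squared, 1)
  # 10% independent noise on the moduli barely hurts the correlation
  set.seed(1)
  Sn <- unclass(S)
  Sn <- Sn * (1 + array(rnorm(length(Sn), 0, 0.1), dim(Sn)))
  Sn <- cross_spectrum(Sn, attr(S, "freqs"))
  expect_gt(fit_metrics(S, Sn)$r_modulus, 0.9)
  # frequency-permuted prediction destroys the correlation
  Sp <- unclass(S)[, , sample(dim(S)[3])]
  Sp <- cross_spectrum(Sp, attr(S, "freqs"))
  expect_lt(abs(fit_metrics(S, Sp)$r_modulus), 0.5)
  # constant vectors are reported as undefined, not an error
  Sc <- cross_spectrum(array(1 + 0i, c(2, 2, 3)), 1:3)
  expect_warning(mc <- fit_metrics(Sc, Sc), "constant")
  expect_true(is.na(mc$r_modulus))
})

test_that("the complexity term is the Gaussian KL and vanishes only at the prior", {
  m0 <- c(0, 0); C0 <- diag(c(0.5, 0.25))
  expect_equal(wmdcm:::kl_gauss(m0, C0, m0, C0), 0)
  expect_gt(wmdcm:::kl_gauss(c(0.1, 0), C0, m0, C0), 0)
  expect_gt(wmdcm:::kl_gauss(m0, 0.5 * C0, m0, C0), 0)
})

test_that("inversion recovers planted modulations with a monotone free energy", {
  arch <- fix_arch3()
  params <- fix_params3()
  planted <- c("node1->node2", "node2->node3")
  th <- theta_init(arch)
  th[paste0("B:", planted)] <- 0.5
  grid <- frequency_grid(2, 100, 2)
  y0 <- simulate_timecourses(params, arch, theta_init(arch), "baseline",
                             duration_s = 96 * 0.8, sampling_rate_hz = 400,
                             seed = 501)
  y1 <- simulate_timecourses(params, arch, th, "early_delay",
                             duration_s = 96 * 0.8, sampling_rate_hz = 400,
                             seed = 502)
  S0 <- estimate_csd(epoch_timecourses(y0, 0.8), grid)
  S1 <- estimate_csd(epoch_timecourses(y1, 0.8), grid)
  post <- invert(S0, S1, params, arch)
  expect_s3_class(post, "dcm_posterior")
  b <- b_posterior(post)$mean
  expect_true(all(b[paste0("B:", planted)] > 0))
  expect_true(all(diff(post$F_trace) >= -1e-3))
  expect_gt(post$fit$r_modulus, 0.9)
  expect_gt(post$complexity, 0)
  # posterior cannot be less certain than the prior (Gaussian shrinkage)
  pv <- post$prior$variance[post$free]
  expect_true(all(diag(post$covariance) <= pv + 1e-10))
  # the two observed windows must share one frequency grid
  S1bad <- estimate_csd(epoch_timecourses(y1, 0.8), frequency_grid(2, 80, 2))
  expect_error(invert(S0, S1bad, params, arch))
})

test_that("data generated at the prior mean keep the posterior near the prior", {
  # self-consistency under noise matched to the observation model: the
  # analytic spectrum plus Hermitian sampling-scale noise, as from ~190
  # taper-epochs
  arch <- fix_arch3()
  params <- fix_params3()
  grid <- frequency_grid(2, 100, 2)
  S <- predicted_csd(params, arch, grid = grid)
  tau <- 1 / sqrt(190)
  covered <- total <- 0
  for (seed in 1:4) {
    set.seed(800 + seed)
    noisy <- function(S) {
      out <- unclass(S)
      for (k in seq_len(dim(S)[3])) {
        d <- Re(diag(S[, , k]))
        E <- matrix(complex(real = rnorm(9), imaginary = rnorm(9)), 3, 3) *
          sqrt(outer(d, d)) * tau / sqrt(2)
        E <- (E + Conj(t(E))) / 2
        out[, , k] <- out[, , k] + E
        diag(out[, , k]) <- pmax(Re(diag(out[, , k])), d * 0.2)
      }
      cross_spectrum(out, attr(S, "freqs"))
    }
    post <- invert(noisy(S), noisy(S), params, arch)
    z <- abs(post$mean) / sqrt(diag(post$covariance))
    covered <- covered + sum(z <= 2)
    total <- total + length(z)
  }
  expect_gte(covered / total, 0.9)
})
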