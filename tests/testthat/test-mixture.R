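test_that("von Mises density normalizes, is symmetric, and hits the uniform limit", {
  expect_equal(vonmises_density(0.7, 0), 1 / (2 * pi), tolerance = 1e-12)
  expect_equal(vonmises_density(1.3, 5), vonmises_density(-1.3, 5))
  for (k in c(0.5, 4, 20)) {
    q <- integrate(function(x) vonmises_density(x, k), -pi, pi,
                   rel.tol = 1e-10)
    expect_equal(q$value, 1, tolerance = 1e-8)
  }
  expect_error(vonmises_density(0, -1), "kappa")
})

test_that("mixture density reduces correctly and integrates to one", {
  tr <- data.frame(target = 0.4, reported = 0.1,
                   nontarget1 = -1.2, nontarget2 = 2.0)
  # pure guessing: flat at 1/(2*pi)
  pg <- mixture_params(kappa = 8, gamma = 1, beta = 0)
  for (th in c(-3, 0, 1, 3)) {
    tr$reported <- th
    expect_equal(mixture_density(tr, pg), 1 / (2 * pi), tolerance = 1e-12)
  }
  # single component: von Mises about the target
  p1 <- mixture_params(kappa = 8, gamma = 0, beta = 0)
  tr$reported <- 0.9
  expect_equal(mixture_density(tr, p1),
               vonmises_density(0.9 - 0.4, 8), tolerance = 1e-12)
  # quadrature over the reported angle
  pm <- mixture_params(kappa = 8, gamma = 0.1, beta = 0.15)
  f <- function(th) vapply(th, function(t) {
    tr$reported <- t
    mixture_density(tr, pm)
  }, numeric(1))
  expect_equal(integrate(f, -pi, pi, rel.tol = 1e-10)$value, 1,
               tolerance = 1e-8)
  # floor at gamma / (2*pi)
  tr$reported <- pi - 0.01
  expect_gte(mixture_density(tr, pm), 0.1 / (2 * pi))
})

test_that("responsibilities normalize and respect the components", {
  pm <- mixture_params(kappa = 8, gamma = 0.1, beta = 0.1)
  set.seed(3)
  tr <- data.frame(target = runif(50, -pi, pi),
                   reported = runif(50, -pi, pi),
                   nontarget1 = runif(50, -pi, pi),
                   nontarget2 = runif(50, -pi, pi))
  r <- responsibilities(tr, pm)
  expect_true(all(as.matrix(r) >= 0 & as.matrix(r) <= 1))
  expect_equal(rowSums(as.matrix(r)), rep(1, 50), tolerance = 1e-10)
  # gamma = 1: all mass on the guess component
  r1 <- responsibilities(tr, mixture_params(kappa = 8, gamma = 1, beta = 0))
  expect_equal(r1$p_guess, rep(1, 50))
  # report at target, far from non-targets: decisively a target response
  tr2 <- data.frame(target = 0, reported = 0, nontarget1 = 2.5,
                    nontarget2 = -2.5)
  r2 <- responsibilities(tr2, mixture_params(kappa = 8, gamma = 0.1,
                                             beta = 0.1))
  expect_gt(r2$p_target, 0.9)
})

test_that("p_target is monotone non-increasing in report-target distance", {
  pm <- mixture_params(kappa = 8, gamma = 0.1, beta = 0.15)
  dist <- seq(0, pi - 0.05, length.out = 40)
  tr <- data.frame(target = 0, reported = dist, nontarget1 = 2.8,
                   nontarget2 = -2.8)
  pt <- responsibilities(tr, pm)$p_target
  expect_true(all(diff(pt) <= 1e-12))
})

test_that("EM recovers mixture parameters and matches the grid-search oracle", {
  d <- fix_reports(n_trials = 700, seed = 11)
  fit <- fit_mixture(d)
  expect_lt(abs(fit$params$gamma - 0.10), 0.03)
  expect_lt(abs(fit$params$beta - 0.15), 0.03)
  expect_lt(abs(fit$params$kappa - 8) / 8, 0.15)
  # EM log-likelihood must not fall below a coarse exhaustive search
  d200 <- d[d$trial <= 67, ]
  em <- fit_mixture(d200)
  oracle <- grid_search_mixture(d200)
  expect_gte(em$loglik, oracle$loglik - 0.1)
})

test_that("degenerate truths are recovered at the boundary", {
  d0 <- simulate_behavior(behavior_sim_spec(n_trials = 700, kappa = 8,
                                            gamma = 0, beta = 0, seed = 5))
  expect_true(all(d0$true_component == "target"))
  fit <- fit_mixture(d0)
  expect_lt(fit$params$gamma, 0.02)
  expect_lt(fit$params$beta, 0.02)
  # uniform reports: dominated by the guess component
  set.seed(8)
  du <- data.frame(trial = rep(1:700, each = 3), report_index = 1:3,
                   target = runif(2100, -pi, pi),
                   nontarget1 = runif(2100, -pi, pi),
                   nontarget2 = runif(2100, -pi, pi),
                   reported = runif(2100, -pi, pi))
  fu <- fit_mixture(du)
  expect_gt(fu$params$gamma, 0.8)
  oracle <- grid_search_mixture(du[du$trial <= 67, ])
  expect_gt(oracle$params$gamma, 0.8)
})

test_that("kappa/sigma mappings are mutually inverse and monotone", {
  k <- c(0.5, 2, 8, 32)
  s <- kappa_to_sigma(k)
  expect_true(all(diff(s) < 0))
  expect_equal(sigma_to_kappa(s), k, tolerance = 1e-6)
})
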