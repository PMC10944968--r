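# analytic hierarchical-Gaussian posterior through the marginal-covariance
# route: independent algebra from the precision route used by peb_fit
gls_oracle <- function(posteriors, X, gamma, prior_var2 = 1/8) {
  p <- length(posteriors[[1]]$mean)
  n <- length(posteriors)
  mu <- unlist(lapply(posteriors, `[[`, "mean"), use.names = FALSE)
  Z <- kronecker(as.matrix(X), diag(p))
  C2 <- diag(prior_var2, p * ncol(X))
  V <- matrix(0, n * p, n * p)
  for (i in seq_len(n)) {
    idx <- (i - 1) * p + seq_len(p)
    V[idx, idx] <- posteriors[[i]]$covariance + diag(exp(gamma), p)
  }
  # posterior mean via C2 Z' (Z C2 Z' + V)^-1 mu
  G <- Z %*% C2 %*% t(Z) + V
  drop(C2 %*% t(Z) %*% solve(G, mu))
}

test_that("peb matches the analytic hierarchical-Gaussian solution", {
  set.seed(2)
  pn <- paste0("b", 1:4)
  X <- cbind(1, c(-1, -1, 1, 1, 0, 0))
  posts <- simulate_peb_inputs(6, pn, X, matrix(rnorm(8, 0, 0.3), 4, 2),
                               between_sd = 0.15, first_level_sd = 0.1,
                               seed = 3)
  fit <- peb_fit(posts, X)
  oracle <- gls_oracle(posts, X, fit$gamma)
  expect_equal(as.numeric(fit$mean), oracle, tolerance = 1e-8)
})

test_that("identical first-level posteriors yield the shared mean under shrinkage", {
  m <- c(b1 = 0.3, b2 = -0.2)
  post <- list(mean = m, covariance = diag(0.01, 2))
  fit <- peb_fit(rep(list(post), 6), matrix(1, 6, 1))
  expect_equal(unname(fit$mean[, 1]), unname(m), tolerance = 0.02)
})

test_that("uncertain subjects are monotonically down-weighted", {
  set.seed(9)
  pn <- "b1"
  base <- lapply(1:6, function(i)
    list(mean = c(b1 = c(1, 1, 1, 1, 1, -1)[i]),
         covariance = matrix(0.01)))
  X <- matrix(1, 6, 1)
  est <- vapply(c(1, 10, 100, 1000), function(f) {
    posts <- base
    posts[[6]]$covariance <- matrix(0.01 * f)
    peb_fit(posts, X)$mean[1, 1]
  }, numeric(1))
  # the discordant subject loses influence as its variance is inflated
  expect_true(all(diff(est) > 0))
})

test_that("a planted group contrast is estimated and flagged; nulls are not", {
  n <- 20
  pn <- paste0("b", 1:6)
  set.seed(4)
  x <- scale(rnorm(n))[, 1]
  X <- cbind(1, x)
  th2 <- matrix(0, 6, 2)
  th2[3, 2] <- 0.5
  posts <- simulate_peb_inputs(n, pn, X, th2, between_sd = 0.2,
                               first_level_sd = 0.1, seed = 6)
  fit <- peb_fit(posts, X)
  expect_lt(abs(fit$mean[3, 2] - 0.5), 0.15)
  pp <- vapply(1:6, function(j) posterior_probability(fit, j, 2), numeric(1))
  expect_true(all(pp >= 0 & pp <= 1))
  expect_gt(pp[3], 0.95)
  expect_true(mean(pp[-3] < 0.95) >= 0.8)
})

test_that("swapping the contrast flips signs and preserves posterior probabilities", {
  n <- 12
  pn <- paste0("b", 1:4)
  set.seed(7)
  x <- rep(c(1, -1), 6)
  X1 <- cbind(1, x)
  X2 <- cbind(1, -x)
  th2 <- matrix(0, 4, 2); th2[2, 2] <- 0.4
  posts <- simulate_peb_inputs(n, pn, X1, th2, 0.15, 0.1, seed = 8)
  f1 <- peb_fit(posts, X1)
  f2 <- peb_fit(posts, X2)
  expect_equal(f1$mean[, 2], -f2$mean[, 2], tolerance = 1e-6)
  pp1 <- vapply(1:4, function(j) posterior_probability(f1, j, 2), numeric(1))
  pp2 <- vapply(1:4, function(j) posterior_probability(f2, j, 2), numeric(1))
  expect_equal(pp1, pp2, tolerance = 1e-6)
})

test_that("leave-one-out prediction works on a near-deterministic linear fixture", {
  n <- 12
  pn <- paste0("b", 1:3)
  set.seed(11)
  x <- scale(rnorm(n))[, 1]
  X <- cbind(1, x)
  th2 <- matrix(0, 3, 2); th2[1, 2] <- 1
  posts <- simulate_peb_inputs(n, pn, X, th2, between_sd = 0.01,
                               first_level_sd = 0.01, seed = 12)
  loo <- loo_cv(posts, X, seed = 1)
  expect_gt(loo$r, 0.9)
  expect_lt(loo$p_value, 0.05)
  expect_error(loo_cv(posts[1:4], X[1:4, ]), "at least 5")
  expect_warning(loo_cv(posts, cbind(1, rep(2, n))), "constant")
})

test_that("contrast report applies both gates and is monotone in the Pp threshold", {
  n <- 20
  pn <- paste0("b", 1:6)
  set.seed(13)
  x <- scale(rnorm(n))[, 1]
  X <- cbind(1, x)
  th2 <- matrix(0, 6, 2); th2[4, 2] <- 0.5
  posts <- simulate_peb_inputs(n, pn, X, th2, 0.2, 0.1, seed = 14)
  fit <- peb_fit(posts, X)
  loo <- loo_cv(posts, X, seed = 2)
  rep95 <- contrast_report(fit, loo, threshold_pp = 0.95)
  rep50 <- contrast_report(fit, loo, threshold_pp = 0.50)
  expect_true(all(rep95$parameter[rep95$selected] %in%
                    rep50$parameter[rep50$selected]))
  if (any(rep95$selected)) {
    expect_true("b4" %in% rep95$parameter[rep95$selected])
    expect_equal(rep95$sign[rep95$parameter == "b4"], "positive")
  }
  # no-effect model: nothing survives a strict gate
  posts0 <- simulate_peb_inputs(n, pn, X, matrix(0, 6, 2), 0.2, 0.1,
                                seed = 15)
  f0 <- peb_fit(posts0, X)
  loo0 <- loo_cv(posts0, X, seed = 3)
  r0 <- contrast_report(f0, loo0, threshold_pp = 0.9999)
  expect_true(sum(r0$selected) <= 1)
})

test_that("unequal first-level certainty between conditions does not bias the contrast", {
  # emulates unequal trial counts: one condition's first-level posteriors are
  # twice as certain; under a zero true contrast the estimate stays unbiased
  pn <- paste0("b", 1:4)
  n_sub <- 12
  biases <- vapply(1:10, function(seed) {
    X <- cbind(1, rep(c(1, -1), n_sub))
    posts <- list()
    set.seed(seed)
    for (s in seq_len(n_sub)) {
      truth <- rnorm(4, 0, 0.15)
      for (ci in 1:2) {
        sdl <- if (ci == 1) 0.1 else 0.05   # second condition: more trials
        m <- truth + rnorm(4, 0, sdl)
        names(m) <- pn
        posts[[length(posts) + 1]] <- list(mean = m,
                                           covariance = diag(sdl^2, 4))
      }
    }
    mean(peb_fit(posts, X)$mean[, 2])
  }, numeric(1))
  se <- 0.15 / sqrt(length(biases))
  expect_lt(abs(mean(biases)), se)
})

test_that("design-matrix validation catches rank and alignment errors", {
  posts <- simulate_peb_inputs(6, c("b1", "b2"), cbind(1, 1:6),
                               matrix(0, 2, 2), 0.1, 0.1, seed = 1)
  expect_error(peb_fit(posts, cbind(1, c(2, 2, 2, 2, 2, 2))),
               "rank deficient")
  expect_error(peb_fit(posts, matrix(1, 5, 1)), "align")
  posts[[2]]$mean <- rev(posts[[2]]$mean)
  expect_error(peb_fit(posts, matrix(1, 6, 1)), "ordering")
})
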