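test_that("dpss tapers are orthonormal and band-concentrated", {
  h <- dpss_tapers(320, nw = 1.6)
  expect_equal(ncol(h), 2)
  expect_equal(crossprod(h), diag(2), tolerance = 1e-8)
  # leading taper concentrates its energy inside the design band
  H <- abs(fft(c(h[, 1], rep(0, 320 * 7))))^2
  inband <- sum(H[1:(8 * 2)])     # |f| <= W with 8x zero padding
  expect_gt(inband / (sum(H) / 2), 0.99)
})

test_that("white-noise cross-spectra are flat and near-independent", {
  set.seed(12)
  sr <- 400
  x <- array(rnorm(2 * 320 * 200), c(2, 320, 200))
  attr(x, "sampling_rate") <- sr
  S <- estimate_csd(x, frequency_grid(5, 150, 5))
  # flat two-sided PSD at sigma^2 * dt
  expect_equal(mean(Re(S[1, 1, ])), 1 / sr, tolerance = 0.05)
  coh <- coherence(S)
  expect_lt(mean(coh[1, 2, ]), 0.1)
  # identical channels are perfectly coherent
  x2 <- x; x2[2, , ] <- x2[1, , ]
  coh2 <- coherence(estimate_csd(x2, frequency_grid(5, 150, 5)))
  expect_equal(as.numeric(coh2[1, 2, ]), rep(1, dim(coh2)[3]),
               tolerance = 1e-9)
})

test_that("a sinusoid produces a diagonal peak at its frequency", {
  sr <- 400
  t <- seq(0, 0.8 - 1 / sr, by = 1 / sr)
  set.seed(2)
  x <- array(0, c(1, length(t), 50))
  for (ep in 1:50)
    x[1, , ep] <- sin(2 * pi * 10 * t + runif(1, 0, 2 * pi)) +
      rnorm(length(t), 0, 0.1)
  attr(x, "sampling_rate") <- sr
  S <- estimate_csd(x, frequency_grid(2, 40, 1))
  expect_equal(frequency_grid(2, 40, 1)$freqs[which.max(Re(S[1, 1, ]))], 10)
})

test_that("window bookkeeping keeps the canonical windows clear of stimulus and report", {
  wins <- canonical_windows()
  expect_length(wins, 3)
  for (w in wins) {
    expect_equal(w$end_ms - w$start_ms, 800)
    # at least 100 ms from the stimulus interval (0-200) and report (2200-)
    expect_true(w$end_ms <= -100 || w$start_ms >= 300)
    expect_lte(w$end_ms, 2100)
  }
  # slicing honors the epoch time axis
  x <- array(seq_len(2 * 3700), c(2, 3700, 1))
  attr(x, "sampling_rate") <- 1000
  sl <- wmdcm:::slice_window(x, epoch_window("early_delay"), 1000, -1000)
  expect_equal(dim(sl)[2], 800)
  expect_error(wmdcm:::slice_window(x, epoch_window("x", 2600, 3000),
                                    1000, -1000), "outside")
})

test_that("estimate_csd rejects inadequate epochs with a helpful message", {
  x <- array(rnorm(2 * 100 * 4), c(2, 100, 4))
  attr(x, "sampling_rate") <- 400
  expect_error(estimate_csd(x, frequency_grid(2, 100, 1)), "epoch too short")
  expect_error(estimate_csd(x, frequency_grid(10, 300, 10)), "Nyquist")
})

test_that("multitaper estimate converges to the analytic model spectrum", {
  # shared oracle with the forward model: a moderate simulation should match
  # the analytic prediction within sampling error at the spectral peak
  arch <- fix_arch3()
  ep <- fix_epochs(n_epochs = 120, seed = 77)
  grid <- frequency_grid(2, 100, 2)
  Shat <- estimate_csd(ep, grid)
  S <- predicted_csd(fix_params3(), arch, grid = grid)
  for (i in 1:3) {
    pk <- which.max(Re(S[i, i, ]))
    rel <- abs(Re(Shat[i, i, pk]) - Re(S[i, i, pk])) / Re(S[i, i, pk])
    expect_lt(rel, 0.25)
  }
})

test_that("colored noise reproduces a requested power-law spectrum", {
  set.seed(5)
  n <- 2^14; dt <- 1 / 400
  psd <- function(f) 2 * (f^-1 + 0.5)
  x <- matrix(colored_noise(n, dt, psd), 1)
  attr(x, "sampling_rate") <- 400
  ep <- array(x[, 1:(400 * 40)], c(1, 400, 40))
  attr(ep, "sampling_rate") <- 400
  S <- estimate_csd(ep, frequency_grid(5, 100, 5))
  f <- frequency_grid(5, 100, 5)$freqs
  rel <- abs(Re(S[1, 1, ]) - psd(f)) / psd(f)
  expect_lt(median(rel), 0.2)
})
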