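#' Prior specification over the log-scaling parameters
#'
#' Zero-mean Gaussian priors with one variance per parameter class.
#' Parameters with zero prior variance are fixed at their prior mean and
#' excluded from the search.
#'
#' @param arch a [network_architecture()].
#' @param v_A,v_B,v_g,v_u,v_obs prior variances for the extrinsic coupling
#'   scalings, condition modulations, intrinsic self-gain scalings,
#'   innovations amplitude scalings, and observation gain scalings.
#' @return object of class `prior_spec`: named vectors `mean` and
#'   `variance` over [theta_names()].
#' @export
prior_spec <- function(arch, v_A = 1/8, v_B = 1/8, v_g = 1/16,
                       v_u = 1/8, v_obs = 1/64) {
  nm <- theta_names(arch)
  v <- numeric(length(nm))
  v[grepl("^A:", nm)] <- v_A
  v[grepl("^B:", nm)] <- v_B
  v[grepl("^g:", nm)] <- v_g
  v[grepl("^u:", nm)] <- v_u
  v[grepl("^obs:", nm)] <- v_obs
  if (any(v < 0)) stop("prior variances must be >= 0")
  structure(list(mean = stats::setNames(numeric(length(nm)), nm),
                 variance = stats::setNames(v, nm)),
            class = "prior_spec")
}

# vectorize the unique entries of a cross-spectrum: real diagonal, and
# real+imaginary parts of the upper triangle, over all frequencies.
vec_csd <- function(cs) {
  n <- dim(cs)[1]; nf <- dim(cs)[3]
  out <- c()
  ut <- which(upper.tri(matrix(0, n, n)))
  for (k in seq_len(nf)) {
    Sk <- cs[, , k]
    out <- c(out, Re(diag(Sk)), Re(Sk[ut]), Im(Sk[ut]))
  }
  out
}

# Variance-stabilizing weights for the vectorized entries: the sampling
# variance of a multitaper cross-spectral estimate scales as
# S_ii(f) S_jj(f) / dof, so dividing entry (i, j, f) by
# sqrt(S_ii(f) S_jj(f)) from the observed spectrum makes the residuals
# approximately homoscedastic, which the single-precision Gaussian
# likelihood assumes.
vec_csd_weights <- function(cs) {
  n <- dim(cs)[1]; nf <- dim(cs)[3]
  out <- c()
  ut_idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  for (k in seq_len(nf)) {
    d <- pmax(Re(diag(cs[, , k])), .Machine$double.eps)
    w_off <- 1 / sqrt(d[ut_idx[, 1]] * d[ut_idx[, 2]])
    out <- c(out, 1 / d, w_off, w_off)
  }
  out
}

# prediction vector for both windows at parameters theta
csd_prediction <- function(theta, params, arch, grid, condition) {
  s0 <- predicted_csd(params, arch, theta, "baseline", grid)
  s1 <- predicted_csd(params, arch, theta, condition, grid)
  c(vec_csd(s0), vec_csd(s1))
}

#' Fit quality metrics between observed and predicted cross-spectra
#'
#' Pearson correlation between the moduli of all unique cross-spectral
#' entries (`r_modulus`) and the coefficient of determination on the same
#' vectors.
#'
#' @param observed,predicted `cross_spectrum` objects (or lists of them) on
#'   a shared grid.
#' @return list with `r_modulus` and `r_squared` (`NA` with a warning when
#'   the observed vector is constant).
#' @export
fit_metrics <- function(observed, predicted) {
  if (inherits(observed, "cross_spectrum")) observed <- list(observed)
  if (inherits(predicted, "cross_spectrum")) predicted <- list(predicted)
  obs <- unlist(lapply(observed, function(s) {
    n <- dim(s)[1]
    keep <- which(upper.tri(matrix(0, n, n), diag = TRUE))
    as.numeric(apply(s, 3, function(m) Mod(m[keep])))
  }))
  prd <- unlist(lapply(predicted, function(s) {
    n <- dim(s)[1]
    keep <- which(upper.tri(matrix(0, n, n), diag = TRUE))
    as.numeric(apply(s, 3, function(m) Mod(m[keep])))
  }))
  stopifnot(length(obs) == length(prd))
  if (stats::sd(obs) == 0 || stats::sd(prd) == 0) {
    warning("constant modulus vector; correlation undefined")
    return(list(r_modulus = NA_real_, r_squared = NA_real_))
  }
  r <- stats::cor(obs, prd)
  r2 <- 1 - sum((obs - prd)^2) / sum((obs - mean(obs))^2)
  list(r_modulus = r, r_squared = r2)
}

# KL divergence between two Gaussians, KL(N(m1,C1) || N(m0,C0)): the
# complexity term of the free energy. Zero iff the two distributions match.
kl_gauss <- function(m1, C1, m0, C0) {
  p <- length(m1)
  C0inv <- solve(C0)
  dm <- m1 - m0
  as.numeric(
    0.5 * (sum(diag(C0inv %*% C1)) + drop(t(dm) %*% C0inv %*% dm) - p +
             determinant(C0, logarithm = TRUE)$modulus -
             determinant(C1, logarithm = TRUE)$modulus))
}

# Laplace free energy of the Gaussian observation model at (mu, lambda):
# accuracy - complexity, given residual e, posterior covariance Cp,
# prior (m0 restricted, P0inv), hyperprior (lambda0, hv).
vl_free_energy <- function(e, lambda, mu, m0, P0inv, logdetP0, Cp,
                           lambda0, hv) {
  ny <- length(e)
  dm <- mu - m0
  ldCp <- determinant(Cp, logarithm = TRUE)$modulus
  -0.5 * exp(lambda) * sum(e^2) + 0.5 * ny * lambda - 0.5 * ny * log(2 * pi) -
    0.5 * drop(t(dm) %*% P0inv %*% dm) - 0.5 * logdetP0 + 0.5 * ldCp -
    0.5 * (lambda - lambda0)^2 / hv
}

#' Invert the spectral model by variational free-energy optimization
#'
#' Fits the network model jointly to a baseline and a delay-window
#' cross-spectrum under the Laplace approximation. The likelihood treats the
#' vectorized real and imaginary cross-spectral entries as Gaussian with a
#' single log-precision hyperparameter estimated alongside; condition
#' modulations (B) act only on the delay window. Optimization is
#' Gauss-Newton ascent on the free energy with Levenberg-Marquardt damping;
#' steps that do not increase the free energy are rejected with an increased
#' damping, so the accepted-step free-energy trace is non-decreasing.
#'
#' @param csd_baseline,csd_delay observed [cross_spectrum()] objects on a
#'   shared frequency grid.
#' @param params base [microcircuit_params()].
#' @param arch a [network_architecture()].
#' @param priors a [prior_spec()].
#' @param condition condition label attached to the delay window.
#' @param max_iter maximum Gauss-Newton iterations.
#' @param tol_rel free-energy improvement (nats) below which an accepted
#'   step counts as converged; the search stops after `n_converged`
#'   consecutive such steps.
#' @param n_converged consecutive small improvements required.
#' @param fd_step finite-difference step for the prediction derivatives.
#' @param verbose print the free-energy trace.
#' @return object of class `dcm_posterior`: posterior `mean` and
#'   `covariance` over the free parameters, free energy `F`, the
#'   accepted-step trace `F_trace`, `fit` metrics at the posterior mean,
#'   `lambda` (log noise precision) and bookkeeping.
#' @export
invert <- function(csd_baseline, csd_delay, params, arch,
                   priors = prior_spec(arch), condition = "early_delay",
                   max_iter = 64, tol_rel = 1e-2, n_converged = 3,
                   fd_step = 1e-3, verbose = FALSE) {
  f0 <- attr(csd_baseline, "freqs")
  stopifnot(identical(f0, attr(csd_delay, "freqs")))
  grid <- frequency_grid(min(f0), max(f0), f0[2] - f0[1])
  stopifnot(identical(grid$freqs, as.numeric(f0)))

  free <- which(priors$variance > 0)
  m0 <- priors$mean[free]
  P0 <- diag(priors$variance[free], length(free))
  P0inv <- diag(1 / priors$variance[free], length(free))
  logdetP0 <- sum(log(priors$variance[free]))

  w <- c(vec_csd_weights(csd_baseline), vec_csd_weights(csd_delay))
  y <- w * c(vec_csd(csd_baseline), vec_csd(csd_delay))
  ny <- length(y)
  predict_free <- function(mu) {
    th <- priors$mean
    th[free] <- mu
    w * csd_prediction(th, params, arch, grid, condition)
  }

  mu <- m0
  g <- predict_free(mu)
  e <- y - g
  # noise log-precision initialized from the initial residual scale, with a
  # loose hyperprior centred there
  lambda <- log(ny / sum(e^2))
  lambda0 <- lambda
  hv <- 16

  Jp <- NULL
  lm_damp <- 1e-3
  Cp <- solve(exp(lambda) * diag(length(free)) + P0inv)
  Fcur <- vl_free_energy(e, lambda, mu, m0, P0inv, logdetP0, Cp, lambda0, hv)
  F_trace <- Fcur
  n_small <- 0

  for (it in seq_len(max_iter)) {
    # numerical derivatives of the prediction (central differences)
    Jp <- matrix(0, ny, length(free))
    for (j in seq_along(free)) {
      mp <- mu; mp[j] <- mp[j] + fd_step
      mm <- mu; mm[j] <- mm[j] - fd_step
      gp <- tryCatch(predict_free(mp), error = function(err) NULL)
      gm <- tryCatch(predict_free(mm), error = function(err) NULL)
      if (is.null(gp) || is.null(gm)) {
        # instability at the perturbed point: one-sided fallback
        if (is.null(gp) && is.null(gm)) stop(
          "prediction unstable in the neighbourhood of the current estimate")
        if (is.null(gp)) Jp[, j] <- (g - gm) / fd_step
        else Jp[, j] <- (gp - g) / fd_step
      } else Jp[, j] <- (gp - gm) / (2 * fd_step)
    }

    accepted <- FALSE
    for (attempt in 1:8) {
      H <- exp(lambda) * crossprod(Jp) + P0inv
      Hd <- H + lm_damp * diag(diag(H), nrow(H))
      b <- exp(lambda) * drop(crossprod(Jp, e)) - drop(P0inv %*% (mu - m0))
      dmu <- tryCatch(solve(Hd, b), error = function(err) NULL)
      if (!is.null(dmu)) {
        mu_new <- mu + dmu
        g_new <- tryCatch(predict_free(mu_new), error = function(err) NULL)
        if (!is.null(g_new)) {
          e_new <- y - g_new
          JtJ <- crossprod(Jp)
          # hyperparameter update at the candidate point (damped Newton on
          # F); keep the old value if the update does not help
          lam_new <- lambda
          for (h in 1:4) {
            Cp_new <- solve(exp(lam_new) * JtJ + P0inv)
            dF <- -0.5 * exp(lam_new) *
              (sum(e_new^2) + sum(diag(Cp_new %*% JtJ))) +
              0.5 * ny - (lam_new - lambda0) / hv
            d2F <- -0.5 * exp(lam_new) *
              (sum(e_new^2) + sum(diag(Cp_new %*% JtJ))) - 1 / hv
            lam_new <- lam_new - dF / d2F
          }
          F_cand <- vapply(c(lam_new, lambda), function(l)
            vl_free_energy(e_new, l, mu_new, m0, P0inv, logdetP0,
                           solve(exp(l) * JtJ + P0inv), lambda0, hv),
            numeric(1))
          if (!is.finite(F_cand[1]) || F_cand[2] >= F_cand[1])
            lam_new <- lambda
          Cp_new <- solve(exp(lam_new) * JtJ + P0inv)
          F_new <- max(F_cand, na.rm = TRUE)
          if (is.finite(F_new) && F_new > Fcur - 1e-3) {
            n_small <- if (abs(F_new - Fcur) < tol_rel) n_small + 1 else 0
            mu <- mu_new; g <- g_new; e <- e_new
            lambda <- lam_new; Cp <- Cp_new
            Fcur <- max(F_new, Fcur)
            F_trace <- c(F_trace, Fcur)
            lm_damp <- max(lm_damp / 2, 1e-6)
            accepted <- TRUE
            break
          }
        }
      }
      lm_damp <- lm_damp * 8
    }
    if (verbose)
      cat(sprintf("iter %3d  F = %.3f  damp = %.1e  accepted = %s\n",
                  it, Fcur, lm_damp, accepted))
    if (!accepted) break           # no admissible ascent direction left
    if (n_small >= n_converged) break
  }

  th_full <- priors$mean
  th_full[free] <- mu
  pred0 <- predicted_csd(params, arch, th_full, "baseline", grid)
  pred1 <- predicted_csd(params, arch, th_full, condition, grid)
  fit <- fit_metrics(list(csd_baseline, csd_delay), list(pred0, pred1))
  Cp <- (Cp + t(Cp)) / 2
  complexity <- drop(kl_gauss(mu, Cp, m0, P0))
  structure(list(mean = mu, covariance = Cp, F = Fcur, F_trace = F_trace,
                 complexity = complexity,
                 lambda = lambda, fit = fit, free = free,
                 theta = th_full, condition = condition,
                 prior = priors, n_iter = length(F_trace) - 1L),
            class = "dcm_posterior")
}

#' @export
print.dcm_posterior <- function(x, ...) {
  cat(sprintf(
    "dcm_posterior: %d free parameters, F = %.2f after %d accepted steps\n",
    length(x$mean), x$F, x$n_iter))
  cat(sprintf("  fit: r_modulus = %.4f, R^2 = %.4f\n",
              x$fit$r_modulus, x$fit$r_squared))
  invisible(x)
}

#' Extract the posterior over condition-modulation (B) parameters
#'
#' @param post a `dcm_posterior` from [invert()].
#' @return list with `mean` and `covariance` restricted to the B entries.
#' @export
b_posterior <- function(post) {
  nm <- names(post$mean)
  bi <- grep("^B:", nm)
  list(mean = post$mean[bi],
       covariance = post$covariance[bi, bi, drop = FALSE])
}
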