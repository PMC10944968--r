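#' Fit a parametric-empirical-Bayes model over first-level posteriors
#'
#' Hierarchical Gaussian model: each subject's first-level posterior mean is
#' treated as a noisy observation of that subject's true parameters, with
#' its first-level posterior covariance as observation noise, and the true
#' parameters follow a group-level GLM `theta_i = X[i, ] %*% theta2 + eps`
#' with isotropic between-subject covariance `exp(gamma) * I` per parameter.
#' Subjects with larger first-level uncertainty are automatically
#' down-weighted by the precision-weighted combination. The between-subject
#' log-variance `gamma` is estimated by maximizing the (closed-form)
#' marginal likelihood under a weakly informative Gaussian prior.
#'
#' @param posteriors list of per-subject lists with elements `mean` (length
#'   `p`) and `covariance` (`p x p`), all sharing one parameter ordering.
#' @param X design matrix, `n_subjects x n_regressors`, full column rank;
#'   first column conventionally the intercept.
#' @param prior_var2 second-level prior variance per group parameter.
#' @param gamma_prior mean and variance of the Gaussian prior on the
#'   between-subject log-variance.
#' @return object of class `peb_model` with second-level posterior `mean`
#'   (`p x n_regressors`, column per regressor), `covariance`, `gamma`,
#'   free energy `F`, and inputs for downstream reduction.
#' @export
peb_fit <- function(posteriors, X, prior_var2 = 1/8,
                    gamma_prior = c(mean = -4, var = 4)) {
  n <- length(posteriors)
  if (n < 2) stop("PEB requires at least 2 subjects")
  X <- as.matrix(X)
  if (nrow(X) != n) stop("design matrix rows must align with subjects")
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  p <- length(posteriors[[1]]$mean)
  pn <- names(posteriors[[1]]$mean)
  for (s in posteriors) {
    if (length(s$mean) != p || !identical(names(s$mean), pn))
      stop("mismatched parameter ordering across subjects")
  }
  nr <- ncol(X)
  mu <- unlist(lapply(posteriors, `[[`, "mean"), use.names = FALSE)
  Z <- kronecker(X, diag(p))
  C2 <- diag(prior_var2, p * nr)

  # marginal likelihood of the stacked means for a given between-subject
  # log-variance, plus its prior: everything Gaussian, so closed form.
  neg_obj <- function(gamma) {
    -(peb_log_evidence(mu, Z, C2, posteriors, gamma) +
        stats::dnorm(gamma, gamma_prior["mean"], sqrt(gamma_prior["var"]),
                     log = TRUE))
  }
  opt <- stats::optimize(neg_obj, interval = c(-12, 4))
  gamma <- opt$minimum

  W <- precision_blocks(posteriors, gamma)
  H <- t(Z) %*% block_apply(W, Z) + solve(C2)
  m2 <- solve(H, t(Z) %*% block_apply(W, matrix(mu)))
  Cpost <- solve(H)
  Fval <- peb_log_evidence(mu, Z, C2, posteriors, gamma) +
    stats::dnorm(gamma, gamma_prior["mean"], sqrt(gamma_prior["var"]),
                 log = TRUE)
  structure(list(
    mean = matrix(m2, p, nr, dimnames = list(pn, colnames(X))),
    covariance = (Cpost + t(Cpost)) / 2,
    gamma = gamma, F = Fval,
    param_names = pn, X = X, posteriors = posteriors,
    prior_var2 = prior_var2, mu = mu, Z = Z, C2 = C2),
    class = "peb_model")
}

# per-subject precision blocks (Sigma_i + exp(gamma) I)^-1
precision_blocks <- function(posteriors, gamma) {
  lapply(posteriors, function(s) {
    p <- length(s$mean)
    solve(s$covariance + diag(exp(gamma), p))
  })
}

# multiply the block-diagonal precision into a stacked matrix
block_apply <- function(W, M) {
  p <- nrow(W[[1]])
  out <- matrix(0, nrow(M), ncol(M))
  for (i in seq_along(W)) {
    idx <- (i - 1) * p + seq_len(p)
    out[idx, ] <- W[[i]] %*% M[idx, , drop = FALSE]
  }
  out
}

# log marginal likelihood ln N(mu; 0, Z C2 Z' + blockdiag(Sigma_i + e^g I))
peb_log_evidence <- function(mu, Z, C2, posteriors, gamma) {
  n <- length(posteriors)
  p <- length(posteriors[[1]]$mean)
  V <- Z %*% C2 %*% t(Z)
  for (i in seq_len(n)) {
    idx <- (i - 1) * p + seq_len(p)
    V[idx, idx] <- V[idx, idx] + posteriors[[i]]$covariance +
      diag(exp(gamma), p)
  }
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  -0.5 * length(mu) * log(2 * pi) - sum(log(diag(ch))) -
    0.5 * sum(backsolve(ch, mu, transpose = TRUE)^2)
}

#' Posterior probability of a group-level effect
#'
#' Bayesian model reduction on one second-level parameter: the evidence of
#' the full model is compared with the evidence of a reduced model whose
#' prior variance for that parameter is shrunk to (effectively) zero, and
#' the posterior probability of the effect being present is the logistic
#' function of the free-energy difference.
#'
#' @param model a fitted [peb_fit()] model.
#' @param param parameter name (row of `model$mean`) or index.
#' @param regressor regressor name (column of `model$mean`) or index.
#' @return `Pp` in `[0, 1]`.
#' @export
posterior_probability <- function(model, param, regressor = 2) {
  p <- length(model$param_names)
  if (is.character(param)) param <- match(param, model$param_names)
  if (is.character(regressor))
    regressor <- match(regressor, colnames(model$mean))
  j <- (regressor - 1) * p + param
  F_full <- peb_log_evidence(model$mu, model$Z, model$C2,
                             model$posteriors, model$gamma)
  C2r <- model$C2
  C2r[j, j] <- 1e-8
  F_red <- peb_log_evidence(model$mu, model$Z, C2r,
                            model$posteriors, model$gamma)
  stats::plogis(F_full - F_red)
}

#' Leave-one-out cross-validated prediction of the group covariate
#'
#' For each subject in turn, the group model is fitted to the remaining
#' subjects and the left-out subject's covariate (second design-matrix
#' column) is predicted from their first-level posterior means by
#' generalized least squares against the estimated group effects.
#' Predictive accuracy is the Pearson correlation between true and
#' predicted covariates.
#'
#' Leave-one-out predictions are not independent across folds (every pair
#' of folds shares almost all training subjects), so the textbook
#' correlation test is anticonservative here. The p-value is therefore
#' computed against a permutation reference: the whole leave-one-out
#' procedure is re-run with the covariate relabelled across subjects, and
#' the observed correlation is ranked among the permuted ones. The
#' between-subject variance is estimated once from an intercept-only model
#' (which is invariant under covariate relabelling) and held fixed across
#' folds and permutations, making the procedure exchangeable under the
#' null.
#'
#' @param posteriors list of first-level posteriors (see [peb_fit()]).
#' @param X design matrix with an intercept first column and the covariate
#'   of interest second.
#' @param n_perm number of covariate permutations for the reference
#'   distribution.
#' @param prior_var2 second-level prior variance (as in [peb_fit()]).
#' @param seed seed for the permutation draws.
#' @return list with `r`, `p_value`, `predicted`, `observed`, `gamma`.
#' @export
loo_cv <- function(posteriors, X, n_perm = 199, prior_var2 = 1/8,
                   seed = 1) {
  n <- length(posteriors)
  if (n < 5) stop("leave-one-out validation requires at least 5 subjects")
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("X must contain an intercept and a covariate")
  x_true <- X[, 2]
  if (stats::sd(x_true) == 0) {
    warning("constant covariate; predictive correlation undefined")
    return(list(r = NA_real_, p_value = NA_real_,
                predicted = rep(NA_real_, n), observed = x_true))
  }
  p <- length(posteriors[[1]]$mean)
  # between-subject variance from the covariate-free model, held fixed
  gamma0 <- peb_fit(posteriors, matrix(1, n, 1),
                    prior_var2 = prior_var2)$gamma
  A <- precision_blocks(posteriors, gamma0)          # (Sigma_i + e^g I)^-1
  M <- do.call(cbind, lapply(posteriors, `[[`, "mean"))  # p x n
  a <- lapply(seq_len(n), function(i) drop(A[[i]] %*% M[, i]))

  loo_predict <- function(x) {
    S_A <- Reduce(`+`, A)
    S_xA <- Reduce(`+`, Map(function(Ai, xi) xi * Ai, A, x))
    S_x2A <- Reduce(`+`, Map(function(Ai, xi) xi^2 * Ai, A, x))
    S_a <- Reduce(`+`, a)
    S_xa <- Reduce(`+`, Map(function(ai, xi) xi * ai, a, x))
    prior_prec <- diag(1 / prior_var2, 2 * p)
    x_hat <- numeric(n)
    for (i in seq_len(n)) {
      H <- rbind(cbind(S_A - A[[i]], S_xA - x[i] * A[[i]]),
                 cbind(S_xA - x[i] * A[[i]], S_x2A - x[i]^2 * A[[i]])) +
        prior_prec
      rhs <- c(S_a - a[[i]], S_xa - x[i] * a[[i]])
      th2 <- solve(H, rhs)
      alpha <- th2[seq_len(p)]
      beta <- th2[p + seq_len(p)]
      num <- drop(t(beta) %*% A[[i]] %*% (M[, i] - alpha))
      den <- drop(t(beta) %*% A[[i]] %*% beta)
      x_hat[i] <- if (den > 0) num / den else 0
    }
    x_hat
  }

  x_hat <- loo_predict(x_true)
  r_obs <- stats::cor(x_true, x_hat)
  r_perm <- with_substream(seed, "loo_perm", {
    vapply(seq_len(n_perm), function(b) {
      xp <- sample(x_true)
      stats::cor(xp, loo_predict(xp))
    }, numeric(1))
  })
  p_value <- (1 + sum(abs(r_perm) >= abs(r_obs))) / (n_perm + 1)
  list(r = r_obs, p_value = p_value, predicted = x_hat,
       observed = x_true, gamma = gamma0)
}

#' Report group effects passing the evidence and predictive gates
#'
#' @param model a fitted [peb_fit()] model.
#' @param loo_result result of [loo_cv()] for the same design.
#' @param regressor regressor of interest (default the second column).
#' @param threshold_pp posterior-probability gate (default 0.95).
#' @param threshold_p LOO predictive p-value gate (default 0.05,
#'   uncorrected).
#' @return data frame of all (parameter, regressor) effects with columns
#'   `parameter`, `posterior_mean`, `Pp`, `sign`, `loo_r`, `loo_p`,
#'   `selected`; the gated subset has `selected = TRUE`.
#' @export
contrast_report <- function(model, loo_result, regressor = 2,
                            threshold_pp = 0.95, threshold_p = 0.05) {
  pn <- model$param_names
  pp <- vapply(seq_along(pn), function(j)
    posterior_probability(model, j, regressor), numeric(1))
  est <- model$mean[, regressor]
  loo_pass <- is.finite(loo_result$p_value) &&
    loo_result$p_value < threshold_p
  data.frame(parameter = pn,
             posterior_mean = unname(est),
             Pp = pp,
             sign = ifelse(est > 0, "positive", "negative"),
             loo_r = loo_result$r,
             loo_p = loo_result$p_value,
             selected = pp > threshold_pp & loo_pass,
             row.names = NULL)
}

#' Conjugate synthetic first-level posteriors for PEB experiments
#'
#' Generates subject-level "posterior" summaries directly from the
#' hierarchical Gaussian model: true subject parameters are
#' `X[i, ] %*% theta2_true` plus between-subject noise, and each subject's
#' first-level mean is the truth plus estimation noise with the stated
#' first-level covariance. Cheap ground-truth fixture for calibration and
#' power experiments on the second level.
#'
#' @param n_subjects number of subjects.
#' @param param_names names of the first-level parameters.
#' @param X design matrix (`n_subjects` rows).
#' @param theta2_true true group parameters, `p x ncol(X)`.
#' @param between_sd between-subject SD per parameter.
#' @param first_level_sd first-level posterior SD per parameter (recycled).
#' @param seed integer seed.
#' @return list of per-subject `list(mean, covariance)`.
#' @export
simulate_peb_inputs <- function(n_subjects, param_names, X, theta2_true,
                                between_sd = 0.2, first_level_sd = 0.1,
                                seed = 1) {
  p <- length(param_names)
  X <- as.matrix(X)
  theta2_true <- matrix(theta2_true, p, ncol(X))
  first_level_sd <- rep_len(first_level_sd, p)
  with_substream(seed, "peb_inputs", {
    lapply(seq_len(n_subjects), function(i) {
      truth <- drop(theta2_true %*% X[i, ]) +
        stats::rnorm(p, 0, between_sd)
      m <- truth + stats::rnorm(p, 0, first_level_sd)
      names(m) <- param_names
      list(mean = m, covariance = diag(first_level_sd^2, p))
    })
  })
}
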