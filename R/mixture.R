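#' Von Mises density with zero mean
#'
#' Density of the circular normal distribution on `[-pi, pi)` with mean 0 and
#' concentration `kappa`. At `kappa = 0` it reduces to the circular uniform
#' density `1/(2*pi)`. Evaluated in log space so large concentrations do not
#' overflow the Bessel normalizer.
#'
#' @param x angle(s) in radians.
#' @param kappa concentration parameter, `kappa >= 0`.
#' @param log return the log density?
#' @return density values (or log densities).
#' @export
vonmises_density <- function(x, kappa, log = FALSE) {
  if (kappa < 0) stop("kappa must be >= 0")
  # log I0(kappa) via the exponentially scaled Bessel function
  ld <- kappa * cos(x) - kappa -
    log(besselI(kappa, 0, expon.scaled = TRUE)) - log(2 * pi)
  if (log) ld else exp(ld)
}

#' Mixture model parameters for continuous-report errors
#'
#' Container for the three-component mixture of target responses, uniform
#' guesses and non-target (swap) responses. Dispersion is carried as the Von
#' Mises concentration `kappa`; the equivalent circular SD `sigma` is derived.
#'
#' @param kappa Von Mises concentration (>= 0). Exactly one of `kappa`/`sigma`
#'   must be given.
#' @param sigma circular SD in radians, alternative parameterization.
#' @param gamma guess probability, in `[0, 1]`.
#' @param beta swap probability, in `[0, 1]`; `gamma + beta <= 1`.
#' @return an object of class `mixture_params`.
#' @export
mixture_params <- function(kappa = NULL, sigma = NULL, gamma, beta) {
  if (is.null(kappa) == is.null(sigma))
    stop("give exactly one of kappa or sigma")
  if (is.null(kappa)) kappa <- sigma_to_kappa(sigma)
  stopifnot(kappa >= 0, gamma >= 0, beta >= 0)
  if (gamma + beta > 1 + 1e-12) stop("gamma + beta must be <= 1")
  structure(
    list(kappa = kappa, sigma = kappa_to_sigma(kappa),
         gamma = gamma, beta = beta),
    class = "mixture_params")
}

#' @export
print.mixture_params <- function(x, ...) {
  cat(sprintf(
    "mixture_params: kappa = %.3f (sigma = %.1f deg), gamma = %.3f, beta = %.3f\n",
    x$kappa, rad2deg(x$sigma), x$gamma, x$beta))
  invisible(x)
}

# Extract the nontarget matrix (n x m) from a reports table.
nontarget_matrix <- function(reports) {
  cols <- grep("^nontarget", names(reports), value = TRUE)
  if (length(cols) == 0) stop("reports table has no nontarget columns")
  as.matrix(reports[cols])
}

# Per-report log densities of the three components. Returns an n x 3 matrix
# (target, guess, nontarget) of log component-weighted densities.
component_log_density <- function(reports, params) {
  err <- circ_diff(reports$reported, reports$target)
  nt <- nontarget_matrix(reports)
  m <- ncol(nt)
  w_t <- max(0, 1 - params$gamma - params$beta)  # clamp float cancellation
  lt <- log(w_t) + vonmises_density(err, params$kappa, log = TRUE)
  lg <- log(params$gamma) - log(2 * pi)
  # pooled non-target term: beta * (1/m) * sum_i phi(reported - nt_i)
  lnt_each <- vonmises_density(circ_diff(reports$reported, nt), params$kappa,
                               log = TRUE)
  dim(lnt_each) <- dim(nt)
  lmax <- apply(lnt_each, 1, max)
  lnt <- log(params$beta) - log(m) + lmax +
    log(rowSums(exp(lnt_each - lmax)))
  out <- cbind(target = lt, guess = rep(lg, nrow(reports)), nontarget = lnt)
  # a zero weight gives -Inf cleanly
  out[, 1][w_t <= 0] <- -Inf
  if (params$gamma <= 0) out[, 2] <- -Inf
  if (params$beta <= 0) out[, 3] <- -Inf
  out
}

#' Mixture density of a reported angle
#'
#' Evaluates the three-component error model: with probability
#' `1 - beta - gamma` the report is the target plus Von Mises noise, with
#' probability `gamma` it is uniform on the circle, and with probability
#' `beta` it is one of the `m` non-targets (chosen uniformly) plus the same
#' Von Mises noise.
#'
#' @param reports data frame with columns `target`, `reported` and
#'   `nontarget*` (radians).
#' @param params a [mixture_params()] object.
#' @param log return log densities?
#' @return vector of densities of each report.
#' @export
mixture_density <- function(reports, params, log = FALSE) {
  ld <- component_log_density(reports, params)
  lmax <- apply(ld, 1, max)
  ll <- lmax + log(rowSums(exp(ld - lmax)))
  if (log) ll else exp(ll)
}

#' Posterior component responsibilities of each report
#'
#' Given fitted mixture parameters, computes the posterior probability that
#' each report was drawn from the target, guess, or (pooled) non-target
#' component. Computed in log space so that reports far from every component
#' under `gamma = 0` still normalize.
#'
#' @inheritParams mixture_density
#' @return data frame with columns `p_target`, `p_guess`, `p_nontarget`
#'   summing to 1 per row.
#' @export
responsibilities <- function(reports, params) {
  ld <- component_log_density(reports, params)
  lmax <- apply(ld, 1, max)
  p <- exp(ld - lmax)
  p <- p / rowSums(p)
  data.frame(p_target = p[, 1], p_guess = p[, 2], p_nontarget = p[, 3])
}

#' Fit the three-component mixture by maximum likelihood
#'
#' Expectation-maximization over `(kappa, gamma, beta)`: the E-step computes
#' component responsibilities, the M-step updates the weights in closed form
#' and the concentration by numerically inverting the mean-resultant-length
#' equation on the responsibility-weighted errors (pooling target errors and
#' per-non-target errors, which share one `kappa`). Several restarts from
#' dispersed starting points guard against local optima; the best restart is
#' returned.
#'
#' @param reports data frame of reports (`target`, `reported`, `nontarget*`).
#' @param n_restarts number of EM restarts from dispersed starts.
#' @param max_iter maximum EM iterations per restart.
#' @param tol absolute log-likelihood convergence tolerance.
#' @param min_reports minimum number of reports required.
#' @return a list with `params` ([mixture_params()]), `loglik`, `n_iter`,
#'   `boundary` (TRUE when the solution pinned a weight at the simplex
#'   boundary or the data were degenerate).
#' @export
fit_mixture <- function(reports, n_restarts = 5, max_iter = 500,
                        tol = 1e-8, min_reports = 20) {
  n <- nrow(reports)
  if (n < min_reports)
    stop(sprintf("need at least %d reports, got %d", min_reports, n))
  err <- circ_diff(reports$reported, reports$target)
  degenerate <- stats::sd(err) < 1e-12

  starts <- list(
    c(kappa = 8,  gamma = 0.05, beta = 0.05),
    c(kappa = 4,  gamma = 0.20, beta = 0.20),
    c(kappa = 16, gamma = 0.10, beta = 0.30),
    c(kappa = 2,  gamma = 0.40, beta = 0.10),
    c(kappa = 32, gamma = 0.02, beta = 0.02))
  starts <- starts[seq_len(min(n_restarts, length(starts)))]

  best <- NULL
  for (s in starts) {
    fit <- em_mixture_once(reports, s["kappa"], s["gamma"], s["beta"],
                           max_iter, tol)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  best$boundary <- degenerate || best$params$gamma < 1e-6 ||
    best$params$beta < 1e-6 || best$params$kappa > 5e3
  best
}

em_mixture_once <- function(reports, kappa, gamma, beta, max_iter, tol) {
  n <- nrow(reports)
  nt <- nontarget_matrix(reports)
  m <- ncol(nt)
  err_t <- circ_diff(reports$reported, reports$target)
  err_nt <- circ_diff(reports$reported, nt)  # n x m
  dim(err_nt) <- dim(nt)

  # keep weights off the exact boundary so log densities stay finite
  eps <- 1e-8
  ll_old <- -Inf
  n_iter <- 0
  for (it in seq_len(max_iter)) {
    n_iter <- it
    # E-step: responsibilities for target, guess and each nontarget
    lt <- log(max(1 - gamma - beta, eps)) +
      vonmises_density(err_t, kappa, log = TRUE)
    lg <- rep(log(max(gamma, eps)) - log(2 * pi), n)
    lnt <- log(max(beta, eps)) - log(m) +
      vonmises_density(err_nt, kappa, log = TRUE)
    dim(lnt) <- dim(err_nt)
    all_l <- cbind(lt, lg, lnt)
    lmax <- apply(all_l, 1, max)
    w <- exp(all_l - lmax)
    tot <- rowSums(w)
    w <- w / tot
    ll <- sum(lmax + log(tot))

    # M-step: closed-form weights
    r_t <- w[, 1]
    r_g <- w[, 2]
    r_nt <- w[, -(1:2), drop = FALSE]
    gamma <- mean(r_g)
    beta <- mean(rowSums(r_nt))
    # concentration: weighted mean resultant length over target + nontarget
    # centred errors (shared kappa)
    cw <- sum(r_t * cos(err_t)) + sum(r_nt * cos(err_nt))
    sw <- sum(r_t * sin(err_t)) + sum(r_nt * sin(err_nt))
    denom <- sum(r_t) + sum(r_nt)
    if (denom > eps) {
      rbar <- sqrt(cw^2 + sw^2) / denom
      kappa <- a1_inv(rbar)
    }
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(params = mixture_params(kappa = kappa, gamma = gamma, beta = beta),
       loglik = ll, n_iter = n_iter)
}

#' Grid-search maximum likelihood over the mixture parameters
#'
#' Brute-force evaluation of the mixture log-likelihood over a coarse
#' `(kappa, gamma, beta)` grid. Slow but entirely independent of the EM
#' routine; used as a cross-check of [fit_mixture()].
#'
#' @inheritParams fit_mixture
#' @param kappa_grid,gamma_grid,beta_grid grid values to scan.
#' @return list with `params` and `loglik` of the best grid point.
#' @export
grid_search_mixture <- function(reports,
                                kappa_grid = c(1, 2, 4, 6, 8, 12, 16, 24, 32),
                                gamma_grid = seq(0, 1, by = 0.02),
                                beta_grid = seq(0, 0.6, by = 0.02)) {
  best <- list(loglik = -Inf)
  for (k in kappa_grid) for (g in gamma_grid) for (b in beta_grid) {
    if (g + b > 1) next
    p <- mixture_params(kappa = k, gamma = g, beta = b)
    ll <- sum(mixture_density(reports, p, log = TRUE))
    if (ll > best$loglik) best <- list(params = p, loglik = ll)
  }
  best
}
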