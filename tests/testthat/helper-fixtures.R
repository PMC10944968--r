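# Shared fixtures: everything is generated in code, small enough for fast
# unit tests. The heavier recovery experiments live in test-acceptance.R.

fix_arch3 <- function() build_chain_network(3)

fix_params3 <- function() microcircuit_params(fix_arch3())

# a modest behavioral dataset with known mixture ground truth
fix_reports <- function(n_trials = 400, kappa = 8, gamma = 0.10,
                        beta = 0.15, seed = 42) {
  simulate_behavior(behavior_sim_spec(
    n_trials = n_trials, kappa = kappa, gamma = gamma, beta = beta,
    seed = seed))
}

# responsibilities table for a single synthetic trial
fix_resp <- function(pt, pnt) {
  data.frame(p_target = pt, p_nontarget = pnt,
             p_guess = 1 - pt - pnt)
}

# short simulated timecourse set for spectral tests
fix_epochs <- function(n_epochs = 24, seed = 9, arch = fix_arch3(),
                       theta = NULL, condition = "baseline",
                       sampling_rate_hz = 400) {
  y <- simulate_timecourses(
    microcircuit_params(arch), arch, theta, condition,
    duration_s = n_epochs * 0.8, sampling_rate_hz = sampling_rate_hz,
    seed = seed)
  epoch_timecourses(y, 0.8)
}
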