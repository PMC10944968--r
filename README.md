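# wmdcm

Behavior-conditioned spectral dynamic causal modelling of working-memory
networks.

## The problem

In multi-item visual working memory, errors are not all alike: reports can
be slightly imprecise (low accuracy), pure guesses, or *swaps* — confident
reports of the wrong item. If these behavioral outcomes arise from
different large-scale network states, then directed (effective)
connectivity between visual, parietal and frontal sources should differ by
trial type, and in particular the balance of feedforward versus feedback
signaling during the memory delay should depend on performance. `wmdcm`
provides the full analysis chain for this question and a synthetic-data
generator with known ground truth so that every stage can be validated
end-to-end, for researchers working with source-level MEG/EEG timecourses.

## The models

**Behavior.** Report errors follow a three-component mixture,

    p(θ̂) = (1−β−γ) φκ(θ̂−θ) + γ/2π + (β/m) Σᵢ φκ(θ̂−θ*ᵢ),

with Von Mises noise φκ, guess probability γ and swap probability β,
fitted per subject by EM. Posterior responsibilities classify trials:
high accuracy (target responsibility > 0.9 in all three reports), swap
(pooled non-target responsibility > 0.7 in any report), else low accuracy.

**Network.** Each of 7 sources (bilateral EVC, IPS, MFG + midline SFG) is a
four-population conductance-based microcircuit (spiny stellate,
superficial pyramidal, inhibitory interneuron, deep pyramidal) with
Morris–Lecar-type dynamics `C V̇ = Σk gk(Vk − V) + u`. Extrinsic edges
follow laminar rules — feedforward sp→ss, feedback dp→{ii, sp}, lateral
both — giving 12 feedforward, 12 feedback and 6 lateral connections, all
estimated as log-scaling deviations with delay-specific modulations (B).
Linearization about the fixed point yields the analytic cross-spectral
density `S(f) = M(f) Gu(f) M(f)* + Sε`, the data feature (2–100 Hz).

**Inference.** Models are inverted against multitaper CSD estimates by
Gauss–Newton ascent on the variational free energy (Laplace
approximation); group effects on the modulations are estimated with a
hierarchical parametric-empirical-Bayes model, gated by posterior
probability (Pp > 0.95, via Bayesian model reduction) and leave-one-out
predictive accuracy (Pearson r, permutation-calibrated p < 0.05).

## Worked example

Fit the mixture model to a simulated session and classify its trials:

```r
library(wmdcm)
spec <- behavior_sim_spec(n_trials = 300, kappa = 8, gamma = 0.10,
                          beta = 0.15, seed = 11)
d   <- simulate_behavior(spec)
fit <- fit_mixture(d)
fit$params
#> mixture_params: kappa = 8.184 (sigma = 20.7 deg), gamma = 0.136, beta = 0.119
labs <- classify_trials(d, fit$params)
behavior_summary(d, labs)
#>           label n_trials proportion mean_abs_error_deg
#> 1 high_accuracy       53  0.1766667           11.01771
#> 2  low_accuracy      204  0.6800000           32.29123
#> 3          swap       43  0.1433333           57.79409
```

The recovered γ̂ = 0.136 and β̂ = 0.119 sit near the generating values
(0.10, 0.15) at this session length, and mean absolute error orders as
high accuracy < low accuracy < swap, as the trial definitions imply.

Predict and verify network spectra, then recover a planted modulation:

```r
arch   <- build_chain_network(3)
params <- microcircuit_params(arch)
S      <- predicted_csd(params, arch)            # analytic CSD, 2-100 Hz

th <- theta_init(arch)
th["B:node1->node2"] <- 0.5                      # planted delay modulation
y0 <- simulate_timecourses(params, arch, duration_s = 76.8,
                           sampling_rate_hz = 400, seed = 101)
y1 <- simulate_timecourses(params, arch, th, "early_delay",
                           duration_s = 76.8, sampling_rate_hz = 400,
                           seed = 102)
S0 <- estimate_csd(epoch_timecourses(y0, 0.8))
S1 <- estimate_csd(epoch_timecourses(y1, 0.8))
post <- invert(S0, S1, params, arch)
post
#> dcm_posterior: 21 free parameters, F = 2410.79 after 9 accepted steps
#>   fit: r_modulus = 0.9955, R^2 = 0.9909
b_posterior(post)$mean["B:node1->node2"]
#> B:node1->node2
#>      0.5628145
```

The planted +0.5 log-scaling is recovered with the right sign and
magnitude, with an observed/predicted modulus correlation above 0.99.

The numbered scripts under `analysis/` run the component studies
(behavioral recovery, spectral oracle agreement, inversion recovery, PEB
power and calibration, source selection, and the end-to-end pipeline) and
write their tables under `results/`.

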