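---
title: "Methods: behavior-conditioned spectral DCM for working-memory networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: behavior-conditioned spectral DCM for working-memory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmdcm)
```

# Overview

`wmdcm` implements an analysis chain for asking how trial-by-trial
working-memory performance relates to directed (effective) connectivity in a
cortical network measured with source-level MEG:

1. behavioral trials from a multi-item delayed-estimation task are
   classified into *high accuracy*, *low accuracy* and *swap* types with a
   three-component Von Mises mixture model;
2. a biophysical forward model — a network of four-population
   conductance-based neural-mass microcircuits — predicts the cross-spectral
   density (CSD) of the source timecourses as a function of connectivity;
3. the model is fitted to observed CSDs by variational free-energy
   optimization under the Laplace approximation, separately for a baseline
   window and a delay window, with delay-specific connectivity modulations;
4. modulations are compared across trial types with a hierarchical
   parametric-empirical-Bayes (PEB) model, gated by posterior probability
   and by leave-one-out (LOO) predictive accuracy.

Because the empirical MEG data are not bundled, every stage is exercised on
synthetic data with known ground truth. The synthetic generators are
first-class, tested package code, and all the quantitative claims in this
vignette are computed by the test suite or by `scripts/acceptance.R` —
nothing is asserted that the code does not itself measure.

# Behavioral model

Each report $\hat\theta$ of a target at angle $\theta$ with non-targets
$\theta^*_1,\dots,\theta^*_m$ is modeled as the mixture

$$p(\hat\theta) = (1-\beta-\gamma)\,\phi_\kappa(\hat\theta-\theta)
  + \gamma\,\tfrac{1}{2\pi}
  + \beta\,\tfrac{1}{m}\sum_{i=1}^m \phi_\kappa(\hat\theta-\theta^*_i),$$

where $\phi_\kappa$ is the zero-mean Von Mises density, $\gamma$ is the
guess probability and $\beta$ the swap probability. Dispersion is carried
internally as the concentration $\kappa$; the equivalent circular SD uses
the standard mapping $\sigma = \sqrt{-2\log(I_1(\kappa)/I_0(\kappa))}$, and
both parameterizations are accepted (`kappa =` or `sigma =`). Swap reports
share the target component's $\kappa$, matching the single $\phi$ in the
mixture.

Fitting is by EM: responsibilities in the E-step; closed-form weight
updates and a numerical inversion of the mean-resultant-length equation for
$\kappa$ in the M-step; five restarts from dispersed starting points. A
coarse exhaustive grid search over $(\kappa,\gamma,\beta)$ is kept in the
package (`grid_search_mixture()`) purely as an independent oracle for the
tests. Degenerate data (e.g. all reports identical) are flagged as boundary
solutions rather than raising errors.

Trial types use per-report posterior responsibilities: *high accuracy*
requires target responsibility above 0.9 in all three reports; otherwise
*swap* requires pooled non-target responsibility above 0.7 in at least one
report (pooled over the $m$ non-targets, since $\beta$ is one pooled
component); the rest are *low accuracy*. Because $0.9 + 0.7 > 1$, the two
gates cannot fire within one report, and the rule order (high-accuracy
first) is fixed only for determinism. Errors are reported in degrees; all
angle arithmetic wraps to $[-\pi,\pi)$.

The behavioral generator reproduces the task's spatial layout: item
locations on an isoeccentric semicircle in one hemifield, minimum pairwise
separation 15° of polar angle, and a 10° exclusion zone around the vertical
meridian, sampled by rejection with a retry cap.

# The forward model

Each network node is a cortical-column microcircuit with four populations —
spiny stellate (ss), superficial pyramidal (sp), inhibitory interneuron
(ii) and deep pyramidal (dp). Population dynamics follow the
conductance-based (Morris–Lecar-type) form

$$C\dot V = g_L(V_L - V) + g_E(V_E - V) + g_I(V_I - V) + u,$$
$$\dot g_k = \kappa_k\big(\textstyle\sum_j w_{kj}\,\varsigma(V_j) - g_k\big),$$

with AMPA-like excitatory and GABA-A-like inhibitory channels and a
logistic firing-rate function $\varsigma$. The hidden state per population
is $(V, g_E, g_I)$.

Within a node, excitatory connections run ss↔sp and sp→dp, all three
excitatory populations connect reciprocally with the interneurons, and all
populations carry inhibitory self-connections modeling synaptic gain.
Between nodes, the laminar rules are: feedforward edges project sp→ss of
the target; feedback edges project dp→{ii, sp}; lateral edges carry both
projection sets at half weight each. These two choices — which excitatory
populations drive the interneurons, and the equal weighting of the two
lateral components — are under-determined descriptively, so both defaults
are explicit and configurable.

The default 7-node architecture has bilateral EVC, IPS and MFG plus a
midline SFG node, with hierarchy ranks EVC(1) < IPS(2) < SFG(3) < MFG(4).
Within each hemispheric chain every lower node projects feedforward to
every higher node (SFG participates in both chains), each feedforward edge
has a feedback reverse, and the three homologous pairs are laterally
connected in both directions: exactly 12 feedforward, 12 feedback and 6
lateral edges, all condition-modulatable. Placing SFG below MFG makes the
MFG→SFG direction a feedback connection; the alternative SFG-on-top
ordering ships as a preset (`build_default_network(sfg_rank = 5)`).

Numerical constants (capacitances, rate constants, reversal potentials,
sigmoid parameters, coupling strengths) are the package's own defaults,
chosen once so that the default network has a stable fixed point with a
clear spectral resonance inside the 2–100 Hz analysis band (an alpha-band
peak near 10 Hz with the shipped values); no claim is made of numerical
equality with any other implementation. All connectivity-related
parameters are estimated as log-scaling deviations from these defaults, so
positive effective coupling is automatic, and condition modulation
multiplies a modulated edge by $e^{B}$ ($B=0$ is an exact identity, which
the tests check).

## Spectral predictions

The deterministic system is linearized about its fixed point (damped
Newton from the leak equilibrium; analytic Jacobian, cross-checked against
finite differences). With innovations $w$ entering the spiny stellate
populations and observed signals $y_i$ taken as the (demeaned) superficial
pyramidal potential per node, the predicted CSD at frequency $f$ is

$$S(f) = M(f)\,\mathrm{diag}(G_u(f))\,M(f)^* + S_\epsilon,\qquad
M(f) = L\,(2\pi i f\,\mathbb{I} - J)^{-1} D,$$

where $G_u(f) = a^2(f^{-\beta_u} + c)$ is a per-node power-law-plus-floor
innovations spectrum and $S_\epsilon$ a flat observation-noise spectrum.
$S(f)$ is Hermitian positive semidefinite by construction. Unstable
parameterizations (any Jacobian eigenvalue with non-negative real part)
refuse to produce spectra or simulations.

Stochastic realizations use Euler–Maruyama integration (compiled code) on
a grid four times finer than the output sampling rate, with innovations
pre-generated in the frequency domain to match $G_u$ exactly, the initial
transient discarded, and white observation noise added at the output rate.
The central oracle of the whole module is that multitaper estimates from
long simulations converge to the analytic $S(f)$; the acceptance suite
checks agreement within 20% relative error at each node's spectral peak on
a 300 s run (measured: ~7%).

# Cross-spectral estimation

Observed CSDs are multitaper estimates with discrete prolate spheroidal
(Slepian) tapers computed from the standard tridiagonal eigenproblem,
half-bandwidth 2 Hz by default, per-epoch demeaning (optional linear
detrending), averaged over tapers and epochs, interpolated to the analysis
grid (default 2–100 Hz in 1 Hz steps), and Hermitian-symmetrized. The
scaling is a two-sided power spectral density, matching `predicted_csd()`
exactly — this shared convention is what makes the simulation/analytic
cross-check meaningful. The three canonical 800 ms analysis windows
(baseline −900 to −100 ms, early delay 400–1200 ms, late delay
1200–2000 ms) keep at least 100 ms clear of stimulus and report intervals;
window bookkeeping is enforced by `epoch_window()` and checked in tests.

# Model inversion

`invert()` fits one model jointly to a baseline and a delay-window CSD:
extrinsic log-scalings (A) act in both windows; condition modulations (B)
act only in the delay window, mirroring a baseline-corrected delay
estimate. The likelihood treats the vectorized unique CSD entries (real
diagonal, real and imaginary upper triangle, all frequencies, both
windows) as Gaussian with a single log-precision hyperparameter.

Two numerical choices matter:

* **Variance stabilization.** The sampling variance of a multitaper CSD
  entry scales as $S_{ii}S_{jj}/\mathrm{dof}$, so each entry is divided by
  $\sqrt{S_{ii}S_{jj}}$ from the observed spectrum before entering the
  likelihood. Without this, the single-precision Gaussian assumption is
  badly heteroscedastic and the posterior is overconfident; with it,
  self-consistency runs (data generated at the prior mean with matched
  noise) put ≥ 95% of posterior means within 2 posterior SDs of the truth.
* **Ascent with rejection.** Optimization is Gauss–Newton on the free
  energy with Levenberg–Marquardt damping; candidate steps that do not
  increase the free energy are rejected and the damping increased, so the
  accepted-step free-energy trace is non-decreasing by construction (the
  tests assert this with a 10⁻³ tolerance). The noise log-precision is
  updated by damped Newton inside each accepted step. Convergence is
  declared after three consecutive accepted steps improving by less than
  10⁻² nats, with a cap of 64 iterations; derivatives of the spectral
  prediction are central finite differences with step 10⁻³.

Priors are zero-mean Gaussians per parameter class (variance 1/8 for
extrinsic and modulation scalings, 1/16 for intrinsic gains, 1/8 for
innovations amplitudes, 1/64 for observation gains — the tighter
observation prior breaks the near-redundancy between input amplitude and
output gain). Parameters with zero prior variance are fixed. Fit quality
is summarized by the Pearson correlation of observed and predicted
cross-spectral moduli and the coefficient of determination on the same
vectors.

# Group inference

First-level posteriors over the B parameters enter a hierarchical Gaussian
model: subject parameters follow a group GLM $\theta^{(1)}_i = X_i
\theta^{(2)} + \varepsilon_i$ with isotropic between-subject variance
$e^\gamma$ per parameter, and each subject's posterior mean is an
observation of $\theta^{(1)}_i$ with its posterior covariance as noise —
so uncertain subjects are automatically down-weighted. $\gamma$ is
estimated by maximizing the closed-form marginal likelihood under a weakly
informative prior; everything else is conjugate linear algebra, which the
tests verify against an independently coded marginal-covariance oracle to
10⁻⁸.

Per-connection evidence uses Bayesian model reduction: the posterior
probability of an effect is the logistic function of the free-energy
difference between the full model and one whose prior variance for that
entry is shrunk to (effectively) zero. Pairwise trial-type contrasts use a
design with an intercept (commonalities) and a ±1 contrast regressor;
swapping the conditions flips every sign and leaves posterior
probabilities unchanged (tested).

**Leave-one-out validation.** For each held-out subject the group model is
refitted and the subject's covariate predicted from their parameters by
GLS; accuracy is the Pearson correlation between true and predicted
covariates. LOO predictions are *not* independent across folds, and we
measured the naive correlation t-test to be strongly anticonservative
(type-I ≈ 14–21% at nominal 5% with n = 20, reproduced with an independent
OLS reimplementation). The p-value is therefore computed against a
permutation reference: the whole LOO procedure is re-run under covariate
relabelings, with the between-subject variance fixed at its intercept-only
estimate so the statistic is exchangeable under the null. This restores
calibration (measured 3.25% over 400 null replicates) while reporting
exactly the statistic of interest. Effects are reported when they pass
both the Pp > 0.95 gate and the (uncorrected) p < 0.05 predictive gate; no
further multiplicity correction is applied, by design.

# Source selection

Source selection consumes source-level time-frequency power maps (the
beamformer reconstruction that would produce them from sensor data is out
of scope; the module operates on provided or synthetic maps on the
standard 31 × 50 grid). Power is baseline-corrected by relative change
against the trial-averaged baseline, a one-way fixed-effects ANOVA with
trial type as the factor is computed independently in every cell
(vectorized, verified cell-by-cell against `aov`), F values are summed
over the full grid with no thresholding, and each ROI returns the
candidate with the largest collapsed F, ties broken toward the lowest
index. Under the global null, selection is uniform over candidates
(chi-square goodness of fit in the tests). One point of note: the widely
quoted hand value for the 3-group instance {1,2,3},{2,3,4},{3,4,5} is
sometimes stated as F = 2; direct computation (and `aov`) give F = 3
exactly, and the package asserts agreement with the `aov` oracle.

# Synthetic data: what it does and does not emulate

The behavioral generator reproduces the task's mixture structure and
spatial constraints with per-subject $(\sigma, \gamma, \beta)$. The group
generator draws per-subject extrinsic log-scalings (SD 0.1 by default, a
typical between-subject heterogeneity for log-scaled connectivity),
applies ground-truth condition effects on modulated edges, resamples
unstable draws with a warning (bounded retries), and realizes epoched
timecourses through the stochastic integrator. Defaults represent the
study conditions at desk scale: 0.8 s epochs; 96 epochs per condition for
the recovery experiments, comparable to per-trial-type trial counts in a
real session; 400 Hz output sampling for the delay-window analyses and
1000 Hz for the long oracle run; 20 subjects for group experiments; a
planted modulation of +0.5 log-scaling units.

What passing tests do **not** show about real data: the generator's
innovations and observation-noise spectra are the model's own parametric
forms, so recovery results certify the estimation machinery, not the
adequacy of those forms for empirical MEG; there is no head model, sensor
noise, source leakage, artifact structure, or inter-regional conduction
delay; and the real generative noise model of cortical sources is unknown
— the synthetic noise knobs are not claims about the study system.

# Numerical choices and degenerate inputs

* Fixed points: damped Newton, residual tolerance 10⁻⁹, failure names the
  offending node; singular or ill-conditioned linearizations warn rather
  than silently proceeding.
* Integration: Euler–Maruyama at 4× the output rate (explicit-scheme
  accuracy for channel rate constants up to 250 s⁻¹); blow-ups report the
  offending time step.
* The EM concentration update inverts $A_1(\kappa)$ by a series
  approximation refined with Newton steps; weights are clamped away from
  the simplex boundary by 10⁻⁸ inside EM to keep log-densities finite.
* All randomness flows from one root seed through named substreams
  (behavior, subject draws, per-condition innovations, permutations), so
  every fixture and the full pipeline are bit-reproducible; the pipeline
  manifest records the configuration hash and artifact checksums.
* Run artifacts are written as CSV/JSON for tables and metadata and native
  R serialization (`.rds`) for posterior objects and spectra.

# Problem sizes

The shipped experiments are sized for a single CPU: the mixture-recovery
grid uses 27 cells × 2000 trials; the spectral oracle one 300 s
simulation; inversion recovery 10 seeds × 96 epochs × 2 conditions on the
3-node reduced architecture with a 2 Hz analysis step; PEB power and LOO
calibration use the conjugate generator (20 subjects; 100 null
replicates); the end-to-end pipeline fixture uses 5 subjects, 32 epochs
and a 3–60 Hz grid. These sizes are the package's default study
conditions; all are configurable upward.

# Known limitations

* The observed-CSD likelihood is an approximation (Gaussian on weighted
  real/imaginary parts with one precision hyperparameter); it is
  calibrated under matched noise but remains approximate for real data.
* LOO prediction uses posterior-mean effects only (no predictive-variance
  weighting of the GLS projection).
* No Bayesian model comparison across architectures, no conduction
  delays, no laminar inference beyond the four-population abstraction,
  and no alternative neural-mass families.
* The second-level between-subject covariance is a single shared scale
  per parameter class.
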