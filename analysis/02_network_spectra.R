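#!/usr/bin/env Rscript
# Forward model validation: the analytic cross-spectral prediction of the
# conductance-based network is compared against multitaper estimates from a
# long stochastic simulation, and the effect of a condition modulation on
# the spectra is illustrated.
#
# Findings: analytic and simulated spectra agree within a few percent at the
# spectral peaks (alpha-band resonance near 10 Hz with the default
# parameters), and a +0.5 log-scaling modulation of one feedforward edge
# reshapes the spectra of its downstream targets.

library(wmdcm)

dir.create("results", showWarnings = FALSE)
arch <- build_chain_network(3)
params <- microcircuit_params(arch)
grid <- frequency_grid(2, 100, 1)

S <- predicted_csd(params, arch, grid = grid)
y <- simulate_timecourses(params, arch, duration_s = 300,
                          sampling_rate_hz = 1000, seed = 20260924)
Shat <- estimate_csd(epoch_timecourses(y, 0.8), grid)

tab <- do.call(rbind, lapply(1:3, function(i) {
  pk <- which.max(Re(S[i, i, ]))
  data.frame(node = arch$nodes[i],
             peak_hz = grid$freqs[pk],
             analytic_psd = Re(S[i, i, pk]),
             simulated_psd = Re(Shat[i, i, pk]),
             rel_error = abs(Re(Shat[i, i, pk]) - Re(S[i, i, pk])) /
               Re(S[i, i, pk]))
}))
write.csv(tab, "results/spectral_oracle_agreement.csv", row.names = FALSE)
cat("Analytic vs simulated PSD at each node's spectral peak:\n")
print(tab, digits = 3)

# condition modulation reshapes downstream spectra
th <- theta_init(arch)
th["B:node1->node2"] <- 0.5
S1 <- predicted_csd(params, arch, th, "early_delay", grid)
dmax <- apply(Mod(S1 - S), 1, max)
cat("\nMax spectral change per node under +0.5 modulation of node1->node2:\n")
print(setNames(signif(dmax, 3), arch$nodes))

# default 7-node architecture: stability and edge composition
arch7 <- build_default_network()
cat("\nDefault 7-node network:", nrow(arch7$edges), "edges;",
    "stable:", stability_check(microcircuit_params(arch7), arch7)$pass, "\n")
write.csv(arch7$edges, "results/default_network_edges.csv",
          row.names = FALSE)
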