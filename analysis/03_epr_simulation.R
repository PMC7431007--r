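#!/usr/bin/env Rscript
## Forward CW-EPR simulation of the fitted parameter sets, the engine
## cross-check, the high-field "overshoot" diagnosis, and a parameter
## recovery experiment on a seeded synthetic spectrum.

suppressMessages(library(histbrace))
dir.create("results/spectra", showWarnings = FALSE, recursive = TRUE)

systems <- lpmo_spin_systems()
grid <- orientation_grid(31, 16)

for (nm in names(systems)) {
  sp <- simulate_powder(systems[[nm]], grid = grid)
  write_spectrum(sp, file.path("results/spectra", paste0(nm, ".txt")))
}
message("simulated powder spectra for all six parameter sets -> results/spectra/")

## engine cross-check: second-order perturbative vs exact diagonalization
set.seed(20)
check <- do.call(rbind, lapply(
  c("apo_14N_X", "apo_15N_Q", "chitin_14N_X", "chitin_15N_Q"), function(nm) {
    s <- systems[[nm]]
    worst <- 0
    for (r in 1:8) {
      v <- abs(rnorm(3)); v <- v / sqrt(sum(v^2))
      pe <- resonance_fields_perturbative(s, v, shf = FALSE)
      ex <- eigenfields_exact(s, v)
      worst <- max(worst, max(sapply(pe$field, function(b)
        min(abs(ex$field - b)))))
    }
    data.frame(system = nm, worst_dev_mT = worst)
  }))
write.csv(check, "results/engine_crosscheck.csv", row.names = FALSE)
message("\nperturbative vs exact resonance fields (worst over 8 orientations):")
print(check, row.names = FALSE)

## overshoot: the X-band high-field feature is an |A3| effect, not low g1
s <- systems$chitin_14N_X
g1_field <- resonance_field(s$g$g[1], s$mw_frequency_GHz)
comb <- resonance_fields_perturbative(s, c(0, 0, 1), shf = FALSE)
message(sprintf(
  "\novershoot: g1 resonance at %.1f mT, outer g3-manifold line at %.1f mT",
  g1_field, max(comb$field)))
message("the hyperfine comb of the unique axis extends beyond the g1 edge,")
message("so the high-field X-band feature needs no anomalously low g value.")

## parameter recovery on a noisy synthetic spectrum
gridf <- orientation_grid(24, 12)
obs <- synth_spectrum(s, snr = 50, seed = 7, grid = gridf)
init <- s
init$g <- suppressWarnings(g_tensor(s$g$g * c(1.01, 0.995, 1.005)))
init$cuA <- cu_hyperfine(s$cuA$absA * c(1.01, 0.99, 1.01), s$cuA$signs)
fit <- fit_spectrum(obs, init, vary = c("g", "A"), grid = gridf)
rec <- data.frame(parameter = c("g3", "absA3_MHz"),
                  truth = c(s$g$g[3], s$cuA$absA[3]),
                  recovered = c(fit$system$g$g[3], fit$system$cuA$absA[3]))
write.csv(rec, "results/fit_recovery.csv", row.names = FALSE)
message("\nrecovery from an SNR-50 synthetic spectrum (1% perturbed start):")
print(rec, row.names = FALSE)
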