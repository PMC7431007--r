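#!/usr/bin/env Rscript
## Ligand-field decomposition of the Cu hyperfine coupling: what drives the
## large Aiso shift on chitin binding, and the thermodynamic consequence of
## the five- to four-coordinate switch for superoxide binding.

suppressMessages(library(histbrace))
dir.create("results", showWarnings = FALSE)

systems <- lpmo_spin_systems()
tab <- delft_table(systems$apo_14N_X, systems$chitin_14N_X)
write.csv(tab, "results/delft_contributions.csv", row.names = FALSE)
message("contributions to the Cu hyperfine coupling (MHz; perpendicular")
message("columns are leading-order approximations):")
print(tab, digits = 3, row.names = FALSE)

message("\nreading: the spin density stays near 0.8 in all branches, the")
message("dipolar term barely moves, but the Fermi contact roughly doubles")
message("(about -138 to -324 MHz on the positive-A1 branch): the Aiso shift")
message("is a Fermi-contact effect of the coordination-number change, not a")
message("covalency collapse.")

## Equilibrium consequence of the DFT energy difference between the
## five-coordinate and four-coordinate Cu-superoxide adducts.
tc <- thermo_coupling(dE1 = 8.2, dE2 = 0, temperature = 298)
ratio <- stability_ratio(tc)
out <- data.frame(ddE_kcal_mol = tc$ddE, temperature_K = tc$temperature,
                  stability_ratio = ratio)
write.csv(out, "results/superoxide_stability.csv", row.names = FALSE)
message(sprintf(
  "\nddE = %.1f kcal/mol at %d K -> Cu(II)-superoxide %.2e times more stable",
  tc$ddE, tc$temperature, ratio))
message("with substrate bound (dissociative elimination suppressed).")
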