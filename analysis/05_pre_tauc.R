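#!/usr/bin/env Rscript
## Paramagnetic relaxation enhancement and rotational tumbling: tau_c from
## 15N T1/T2, the forward Solomon-Bloembergen PRE profile over a synthetic
## Cu-bearing ensemble, and its comparison to a noisy observed table.

suppressMessages(library(histbrace))
dir.create("results", showWarnings = FALSE)

cfg <- synth_config(seed = 1)
se <- synth_ensemble(cfg)
rel <- synth_relaxation(tau_c_ns = 10.2, cfg)

tc <- estimate_tauc(rel$table, n15_frequency_MHz = rel$truth$nuN_MHz)
message(sprintf(
  "tau_c = %.2f +/- %.2f ns from %d residues (truth 10.2 ns; flexible tail",
  tc$tau_c_ns, tc$uncertainty_ns, tc$n_used))
message("excluded by the hetNOE >= 0.65 and T1/T2 spread filters)")
jsonlite::write_json(tc, "results/tauc.json", auto_unbox = TRUE, digits = NA)

systems <- lpmo_spin_systems()
prof <- predict_pre_profile(se$ensemble, rel$table, tau_c_ns = tc$tau_c_ns,
                            g_iso = systems$apo_14N_X$g$giso)
obs <- synth_intensity_table(prof, sd = 0.05, seed = cfg$seed)
prof$ratio_obs <- obs$ratio_obs
prof$ratio_err <- obs$ratio_err
write.csv(as.data.frame(prof), "results/pre_profile.csv", row.names = FALSE)

near <- prof[prof$r_eff <= 12, ]
message(sprintf(
  "\n%d residues lie within 12 A of the Cu; their predicted intensity",
  nrow(near)))
message(sprintf(
  "ratios are all below %.3f (i.e. more than 80%% signal loss).",
  max(near$ratio_pred)))
sel <- prof$ratio_pred < 0.98
message(sprintf(
  "rank correlation predicted vs observed over the PRE-sensitive region: %.2f",
  cor(prof$ratio_pred[sel], prof$ratio_obs[sel], method = "spearman")))
message("profile written to results/pre_profile.csv")
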