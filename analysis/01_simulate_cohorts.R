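#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study material.
#
# Simulates the ECG cohorts (30 wild-type + 30 Ts65Dn animals, 20 s at
# 5 kHz), one example recording written out in full as delimited text, a
# weaning-litter simulation under allele-specific survival, and the
# aneuploid expression matrix used by stage 4. Everything is seeded, so
# rerunning reproduces the same material byte for byte.

suppressMessages(library(dscardio))
dir.create("results", showWarnings = FALSE)

seed0 <- 1000

# -- example recording (written in full for inspection) ----------------------
rec <- simulate_ecg(make_genotype_preset("Ts65Dn"), duration = 5,
                    sampling_rate = 2000, seed = seed0,
                    animal_id = "example_Ts65Dn")
write_recording(rec, "results/example_Ts65Dn_ecg.csv")
cat("example recording:", rec$animal_id, "-",
    nrow(rec$ground_truth$beats), "beats,",
    nrow(rec$ground_truth$anomalies), "ledger entries\n")

# -- ECG cohorts --------------------------------------------------------------
cohort <- list()
for (g in c("wt", "Ts65Dn")) {
  preset <- make_genotype_preset(g)
  for (i in 1:30) {
    sd_i <- seed0 + 100 * (g == "Ts65Dn") + i
    cohort[[length(cohort) + 1]] <- phenotype_animal(
      preset, seed = sd_i, duration_s = 20, animal_id = paste0(g, "_", i))
  }
}
cohort <- do.call(rbind, cohort)
write.table(cohort, "results/ecg_cohort.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
cat("cohort:", nrow(cohort), "animals -> results/ecg_cohort.tsv\n")

# -- litters under allele-specific survival ----------------------------------
# relative carrier survival 0.515 reproduces the observed 34% weaning rate
lit <- simulate_litters(litter_sim_spec(
  "Ts65Dn_x_F1B6C3B_sim", 617, c(wt = 0.5, Ts65Dn = 0.5),
  c(wt = 1, Ts65Dn = 0.515), seed = seed0))
cat(sprintf("simulated weaning: %d wt, %d Ts65Dn (%.1f%% carriers)\n",
            lit$counts[["wt"]], lit$counts[["Ts65Dn"]],
            100 * attr(lit, "realized_fraction")[["Ts65Dn"]]))

# -- expression matrix --------------------------------------------------------
se <- simulate_expression(expression_sim_spec(
  n_genes = 3000, n_mmu16_tri = 100, n_app_runx1 = 40, n_mmu17_tri = 30,
  seed = seed0))
write_expression(se, "results/expression")
cat("expression matrix:", nrow(se), "genes x", ncol(se),
    "arrays -> results/expression_*.tsv\n")
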