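#!/usr/bin/env Rscript
# Stage 1: generate every synthetic input the downstream stages consume.
# Emulates the study design: three cell-line groups in triplicate at the
# peptide level (with a subset of proteins shifted ~100-fold in the
# resistant lines), two n = 5 serum cohorts at the protein level, MTS
# dose-response readouts and growth records.

suppressPackageStartupMessages(library(exosig))
dir.create("results/inputs", recursive = TRUE, showWarnings = FALSE)
seed <- 11

# peptide-level cell-line comparison: sensitive vs resistant
cell_cfg <- sim_config(
  seed = seed, n_proteins = 400, frac_discriminating = 0.1,
  effect_log2 = log2(100), cv = 0.2, peptides_per_protein_range = c(1, 5),
  # abundance-biased dropout so low-intensity proteins go undetected in some
  # lines, giving nonempty unique-detection Venn regions as in real MS data
  missing_rate = 0.3, missing_mode = "intensity", n_per_group = 3,
  group_labels = c("HMPOS-S", "HMPOS-2.5R", "HMPOS-10R"))
cells <- simulate_peptide_table(cell_cfg)
write_peptide_table(cells$peptides, "results/inputs/cell_peptides.tsv")
write_sample_sheet(cells$samples, "results/inputs/cell_samples.csv")
write_sim_truth(cells$truth, "results/inputs/cell_truth.json")
message(sprintf("cell lines: %d peptides / %d proteins, %d samples, %d truth proteins",
                nrow(cells$peptides), cell_cfg$n_proteins,
                nrow(cells$samples), length(cells$truth$discriminating_ids)))

# protein-level serum cohorts (good vs poor responders)
serum_cfg <- sim_config(
  seed = seed, n_proteins = 500, frac_discriminating = 0.04,
  effect_log2 = 2, cv = 0.2, n_per_group = 5,
  group_labels = c("good", "poor"))
serum <- simulate_serum_cohorts(serum_cfg)
write_protein_table(serum$proteins, "results/inputs/serum_proteins.tsv")
write_sample_sheet(serum$samples, "results/inputs/serum_samples.csv")
write_sim_truth(serum$truth, "results/inputs/serum_truth.json")
message(sprintf("serum cohorts: %d proteins x %d samples, %d discriminating",
                nrow(serum$proteins), ncol(serum$proteins),
                length(serum$truth$discriminating_ids)))

# MTS dose-response readouts at the study's dose ladder, one curve per line
doses <- c(0, 0.5, 1, 2.5, 4, 6, 8, 10)
curves <- list(`HMPOS-S` = 5.62, `HMPOS-2.5R` = 18.2, `HMPOS-10R` = 664.2)
mts <- do.call(rbind, lapply(names(curves), function(line) {
  dr <- simulate_dose_response(curves[[line]], hill = 1, lower = 0, upper = 1,
                               doses = doses, noise_sd = 0.02,
                               seed = seed + match(line, names(curves)),
                               n_replicates = 3)
  cbind(cell_line = line, dr)
}))
write.csv(mts, "results/inputs/mts_viability.csv", row.names = FALSE)
message("MTS: ", nrow(mts), " wells across ", length(curves), " cell lines")

# growth records at the reported doubling times
growth <- do.call(rbind, lapply(
  list(c(27.2), c(41.28), c(43.52)), function(tg) {
    g <- simulate_growth(48, 1e5, tg)
    data.frame(h_elapsed = g$h_elapsed, c1 = g$c1, c2 = g$c2)
  }))
growth$cell_line <- names(curves)
write.csv(growth, "results/inputs/growth_counts.csv", row.names = FALSE)
message("growth records written; inputs complete under results/inputs/")
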