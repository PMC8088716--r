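#!/usr/bin/env Rscript
# Stage 4: cohort assignment from the clinical DFI records, prognosis
# signature training and leave-one-out validation on the serum cohorts.

suppressPackageStartupMessages(library(exosig))
dir.create("results/prognosis", recursive = TRUE, showWarnings = FALSE)

clinical <- read_sample_sheet(
  system.file("extdata", "dog_cohort_clinical.csv", package = "exosig"))
cohorts <- assign_cohorts(clinical, good_min_days = 300, poor_max_days = 100)
write_sample_sheet(cohorts$sheet, "results/prognosis/clinical_cohorts.csv")
message("clinical cohorts: ",
        paste(names(cohorts$counts), cohorts$counts, sep = "=", collapse = ", "))

mat <- read_matrix("results/inputs/serum_proteins.tsv", "protein")
sheet <- read_sample_sheet("results/inputs/serum_samples.csv")

model <- train_signature(mat, sheet, "good", "poor", p_cutoff = 0.05)
jsonlite::write_json(
  list(selected_features = model$selected_features,
       weight = as.list(model$weight),
       boundary = model$boundary, orientation = model$orientation),
  "results/prognosis/signature_model.json", auto_unbox = TRUE, pretty = TRUE)
message(length(model$selected_features), " features selected; boundary ",
        signif(model$boundary, 4))

loo <- loo_accuracy(mat, sheet, "good", "poor", p_cutoff = 0.05)
write.table(loo$decompositions, "results/prognosis/loo_scores.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(format(loo$accuracy), "results/prognosis/loo_accuracy.txt")
message(sprintf("leave-one-out accuracy: %.0f%% (%d/%d)",
                100 * loo$accuracy,
                sum(loo$decompositions$predicted == loo$decompositions$true,
                    na.rm = TRUE),
                nrow(loo$decompositions)))
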