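#!/usr/bin/env Rscript
# Stage 2: peptide-to-protein fold changes by nested geometric medians,
# the 100-fold abundance filter, and the three-way detection Venn.

suppressPackageStartupMessages(library(exosig))
dir.create("results/quantify", recursive = TRUE, showWarnings = FALSE)

tbl <- read_matrix("results/inputs/cell_peptides.tsv", "peptide")
sheet <- read_sample_sheet("results/inputs/cell_samples.csv")

for (resistant in c("HMPOS-2.5R", "HMPOS-10R")) {
  fc <- fold_change_table(tbl, sheet, resistant, "HMPOS-S")
  slug <- gsub("[^A-Za-z0-9]+", "_", resistant)
  write.table(fc, sprintf("results/quantify/fc_%s_vs_S.tsv", slug),
              sep = "\t", quote = FALSE, row.names = FALSE)
  hits <- threshold_filter(fc, 100, "over")
  writeLines(hits, sprintf("results/quantify/hits100_%s.txt", slug))
  message(sprintf("%s vs HMPOS-S: %d proteins quantified, %d at >= 100-fold",
                  resistant, sum(fc$flag == "ok"), length(hits)))
}

# detection Venn over the three groups (protein seen in >= 1 replicate)
m <- as.matrix(tbl[, -(1:2)])
present <- lapply(unique(sheet$group), function(g) {
  cols <- sheet$sample_id[sheet$group == g]
  unique(tbl$protein_id[rowSums(!is.na(m[, cols, drop = FALSE])) > 0])
})
names(present) <- unique(sheet$group)
ds <- detection_sets(present)
jsonlite::write_json(list(counts = as.list(ds$counts), regions = ds$regions),
                     "results/quantify/venn.json", auto_unbox = TRUE,
                     pretty = TRUE)
message("Venn regions: ",
        paste(names(ds$counts), ds$counts, sep = "=", collapse = ", "))
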