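#!/usr/bin/env Rscript
# Stage 5: phenotype assays -- 4PL IC50 fits per cell line and doubling
# times from the growth records.

suppressPackageStartupMessages(library(exosig))
dir.create("results/assays", recursive = TRUE, showWarnings = FALSE)

mts <- read.csv("results/inputs/mts_viability.csv")
fits <- do.call(rbind, lapply(split(mts, mts$cell_line), function(df) {
  fit <- fit_dose_response(df[, c("dose", "viability")])
  data.frame(cell_line = df$cell_line[1], ic50 = fit$ic50, hill = fit$hill,
             lower = fit$lower, upper = fit$upper, rss = fit$rss,
             converged = fit$converged, ic50_in_range = fit$ic50_in_range)
}))
write.csv(fits, "results/assays/ic50_fits.csv", row.names = FALSE)
for (i in seq_len(nrow(fits))) {
  message(sprintf("%s: IC50 %.4g uM%s", fits$cell_line[i], fits$ic50[i],
                  if (fits$ic50_in_range[i]) "" else
                    " (extrapolated beyond the dose ladder)"))
}
resistant <- fits[fits$cell_line %in% c("HMPOS-2.5R", "HMPOS-10R"), ]
message(sprintf("resistant-line IC50 fold difference: %.1f",
                max(resistant$ic50) / min(resistant$ic50)))

growth <- read.csv("results/inputs/growth_counts.csv")
growth$t_gen_hours <- mapply(generation_time, growth$h_elapsed, growth$c1,
                             growth$c2)
write.csv(growth, "results/assays/doubling_times.csv", row.names = FALSE)
message("doubling times (h): ",
        paste(growth$cell_line, round(growth$t_gen_hours, 2),
              sep = "=", collapse = ", "))
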