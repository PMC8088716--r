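# Shared fixtures and independent oracles.

# Build a peptide table by hand: `abund` is a list protein -> list of
# per-peptide numeric vectors (one value per sample, NA = missing).
make_peptide_table <- function(abund, sample_ids) {
  rows <- list()
  pep <- 0L
  for (p in names(abund)) {
    for (v in abund[[p]]) {
      pep <- pep + 1L
      rows[[pep]] <- data.frame(
        peptide_id = sprintf("pep%03d", pep), protein_id = p,
        t(stats::setNames(v, sample_ids)),
        check.names = FALSE, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

make_sheet <- function(sample_ids, groups) {
  data.frame(sample_id = sample_ids, group = groups, cohort = groups,
             replicate = stats::ave(seq_along(groups), groups, FUN = seq_along),
             dfi_days = NA_integer_, stringsAsFactors = FALSE)
}

# Independent brute-force fold-change oracle: materialize every replicate
# ratio with explicit loops and take log-space medians with a hand-rolled
# midpoint rule (no reuse of the package's helpers).
brute_force_fc <- function(pep_values_a, pep_values_b) {
  log_median <- function(x) {
    s <- sort(log(x))
    n <- length(s)
    if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  }
  pep_ratios <- c()
  for (k in seq_along(pep_values_a)) {
    a <- pep_values_a[[k]]
    b <- pep_values_b[[k]]
    a <- a[!is.na(a) & a > 0]
    b <- b[!is.na(b) & b > 0]
    if (length(a) == 0 || length(b) == 0) next
    ratios <- c()
    for (x in a) for (y in b) ratios <- c(ratios, x / y)
    pep_ratios <- c(pep_ratios, exp(log_median(ratios)))
  }
  if (length(pep_ratios) == 0) return(NA_real_)
  exp(log_median(pep_ratios))
}

# Random small quantifier instance: <=5 peptides, <=4 replicates per group,
# optional missingness. Returns the package inputs plus the oracle value.
random_fc_instance <- function() {
  n_pep <- sample(1:5, 1)
  na_ <- sample(2:4, 1)
  nb_ <- sample(2:4, 1)
  samples <- c(paste0("a", seq_len(na_)), paste0("b", seq_len(nb_)))
  groups <- c(rep("A", na_), rep("B", nb_))
  vals_a <- list()
  vals_b <- list()
  abund <- list()
  pep_list <- list()
  for (k in seq_len(n_pep)) {
    a <- exp(stats::rnorm(na_, log(100), 1))
    b <- exp(stats::rnorm(nb_, log(100), 1))
    if (stats::runif(1) < 0.3) a[sample(na_, 1)] <- NA
    if (stats::runif(1) < 0.3) b[sample(nb_, 1)] <- NA
    vals_a[[k]] <- a
    vals_b[[k]] <- b
    pep_list[[k]] <- c(a, b)
  }
  abund <- list(PX = pep_list)
  list(tbl = make_peptide_table(abund, samples),
       sheet = make_sheet(samples, groups),
       oracle = brute_force_fc(vals_a, vals_b))
}

serum_cfg <- function(seed, effect_log2, n_proteins = 500,
                      frac_discriminating = 0.04, cv = 0.2, n_per_group = 5) {
  sim_config(seed = seed, n_proteins = n_proteins,
             frac_discriminating = frac_discriminating,
             effect_log2 = effect_log2, cv = cv, n_per_group = n_per_group,
             group_labels = c("good", "poor"))
}
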