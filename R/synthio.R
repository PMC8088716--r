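#' Simulation configuration
#'
#' Bundles and validates the parameters shared by the synthetic-input
#' generators. The defaults emulate the study design: three-replicate
#' cell-line groups for the peptide generator and two n = 5 serum cohorts
#' for the cohort generator, lognormal label-free intensities, and a small
#' fraction of discriminating proteins carrying a group shift.
#'
#' @param seed integer seed; identical configs are bit-reproducible.
#' @param n_proteins number of proteins to simulate.
#' @param frac_discriminating fraction in \[0, 1\] of proteins flagged as
#'   discriminating; `floor(frac_discriminating * n_proteins)` are flagged.
#' @param effect_log2 mean log2 shift of discriminating proteins between
#'   groups (reference group vs the others / cohort 1 vs cohort 2).
#' @param cv lognormal coefficient of variation of replicate abundances
#'   (> 0); the lognormal sdlog is `sqrt(log(1 + cv^2))`.
#' @param peptides_per_protein_range integer pair (min, max), both >= 1;
#'   peptide multiplicity is drawn uniformly from this range.
#' @param missing_rate fraction in \[0, 1) of peptide-level observations
#'   set to missing.
#' @param missing_mode `"mcar"` (default, missing completely at random) or
#'   `"intensity"` (logistic in log-abundance: low-abundance observations
#'   are more likely to drop, with overall rate approximately
#'   `missing_rate`).
#' @param n_per_group replicates per group (>= 2).
#' @param group_labels character vector of distinct group labels.
#'
#' @return an object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(seed = 1, n_proteins = 50, group_labels = c("A", "B"))
#' @export
sim_config <- function(seed = 1L,
                       n_proteins = 500L,
                       frac_discriminating = 0.04,
                       effect_log2 = 2,
                       cv = 0.2,
                       peptides_per_protein_range = c(1L, 5L),
                       missing_rate = 0,
                       missing_mode = c("mcar", "intensity"),
                       n_per_group = 3L,
                       group_labels = c("HMPOS-S", "HMPOS-2.5R", "HMPOS-10R")) {
  missing_mode <- match.arg(missing_mode)
  if (length(seed) != 1L || !is.finite(seed)) {
    stop_config("seed must be a single finite integer")
  }
  if (length(n_proteins) != 1L || n_proteins < 1) {
    stop_config("n_proteins must be a positive count")
  }
  if (frac_discriminating < 0 || frac_discriminating > 1) {
    stop_config("frac_discriminating must lie in [0, 1]")
  }
  if (cv <= 0) stop_config("cv must be > 0")
  if (length(peptides_per_protein_range) != 2L ||
      any(peptides_per_protein_range < 1) ||
      peptides_per_protein_range[1] > peptides_per_protein_range[2]) {
    stop_config("peptides_per_protein_range must be an increasing integer pair >= 1")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop_config("missing_rate must lie in [0, 1)")
  }
  if (length(n_per_group) != 1L || n_per_group < 2) {
    stop_config("n_per_group must be >= 2")
  }
  if (length(group_labels) < 1L || anyDuplicated(group_labels) ||
      any(!nzchar(group_labels))) {
    stop_config("group_labels must be nonempty and distinct")
  }
  structure(
    list(
      seed = as.integer(seed),
      n_proteins = as.integer(n_proteins),
      frac_discriminating = frac_discriminating,
      effect_log2 = effect_log2,
      cv = cv,
      peptides_per_protein_range = as.integer(peptides_per_protein_range),
      missing_rate = missing_rate,
      missing_mode = missing_mode,
      n_per_group = as.integer(n_per_group),
      group_labels = as.character(group_labels)
    ),
    class = "sim_config"
  )
}

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

sdlog_from_cv <- function(cv) sqrt(log(1 + cv^2))

protein_ids <- function(n) sprintf("PROT%05d", seq_len(n))

new_sim_truth <- function(discriminating_ids, true_log2_effects, cfg) {
  list(
    discriminating_ids = discriminating_ids,
    true_log2_effects = true_log2_effects,
    generating_params = cfg
  )
}

missing_mask <- function(log_abundance, rate, mode) {
  n <- length(log_abundance)
  if (rate <= 0) return(rep(FALSE, n))
  if (mode == "mcar") {
    stats::runif(n) < rate
  } else {
    # Intensity-dependent dropout: logistic in centred, scaled log abundance,
    # rescaled so the expected overall rate is approximately `rate`.
    z <- scale(log_abundance)[, 1]
    p <- stats::plogis(-z)
    p <- p * rate / mean(p)
    stats::runif(n) < pmin(p, 0.99)
  }
}

#' Simulate a peptide-level abundance table
#'
#' Emulates label-free MS input for multi-group cell-line comparisons:
#' lognormal peptide intensities, uniform peptide multiplicity per protein,
#' group shifts on a flagged subset of discriminating proteins (applied to
#' every non-reference group; the first label in `cfg$group_labels` is the
#' reference), and optional missingness. Peptide effects equal their
#' protein's effect, so the quantifier's ground truth is well defined.
#'
#' @param cfg a [sim_config()].
#' @return list with `peptides` (data.frame: `peptide_id`, `protein_id`,
#'   one numeric column per sample; `NA` = missing), `samples` (sample
#'   sheet data.frame), and `truth` (discriminating ids, true log2 effects,
#'   generating params).
#' @examples
#' sim <- simulate_peptide_table(sim_config(seed = 1, n_proteins = 20))
#' head(sim$peptides)
#' @export
simulate_peptide_table <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (length(cfg$group_labels) < 2L) {
    stop_config("simulate_peptide_table needs >= 2 group labels")
  }
  with_seed(cfg$seed, {
    prot <- protein_ids(cfg$n_proteins)
    n_disc <- floor(cfg$frac_discriminating * cfg$n_proteins)
    disc <- if (n_disc > 0) sort(sample(prot, n_disc)) else character(0)
    effects <- stats::setNames(rep(0, cfg$n_proteins), prot)
    effects[disc] <- cfg$effect_log2

    rng <- cfg$peptides_per_protein_range
    n_pep <- sample(seq(rng[1], rng[2]), cfg$n_proteins, replace = TRUE)
    pep_protein <- rep(prot, times = n_pep)
    n_total <- length(pep_protein)
    pep_id <- sprintf("PEP%06d", seq_len(n_total))

    # baseline per-protein log intensity plus a per-peptide ionization offset
    mu_prot <- stats::rnorm(cfg$n_proteins, mean = log(1e6), sd = 1.5)
    mu_pep <- rep(mu_prot, times = n_pep) + stats::rnorm(n_total, sd = 0.5)
    sdl <- sdlog_from_cv(cfg$cv)

    groups <- rep(cfg$group_labels, each = cfg$n_per_group)
    reps <- rep(seq_len(cfg$n_per_group), times = length(cfg$group_labels))
    sample_id <- paste0(gsub("[^A-Za-z0-9.]+", ".", groups), "_r", reps)

    mat <- matrix(NA_real_, n_total, length(sample_id),
                  dimnames = list(pep_id, sample_id))
    for (j in seq_along(sample_id)) {
      shift <- if (groups[j] == cfg$group_labels[1]) 0 else
        effects[pep_protein] * log(2)
      la <- mu_pep + shift + stats::rnorm(n_total, sd = sdl)
      miss <- missing_mask(la, cfg$missing_rate, cfg$missing_mode)
      la[miss] <- NA_real_
      mat[, j] <- exp(la)
    }

    peptides <- data.frame(
      peptide_id = pep_id,
      protein_id = pep_protein,
      mat,
      check.names = FALSE,
      stringsAsFactors = FALSE,
      row.names = NULL
    )
    samples <- data.frame(
      sample_id = sample_id,
      group = groups,
      cohort = NA_character_,
      replicate = reps,
      dfi_days = NA_integer_,
      stringsAsFactors = FALSE
    )
    list(peptides = peptides, samples = samples,
         truth = new_sim_truth(disc, effects, cfg))
  })
}

#' Simulate protein-level serum exosome cohorts
#'
#' Emulates two serum cohorts (good vs poor responders, n per cohort from
#' `cfg$n_per_group`) at the protein level: lognormal abundances with a
#' log2 shift of `cfg$effect_log2` applied to the discriminating proteins
#' in the second cohort.
#'
#' @param cfg a [sim_config()] with exactly two `group_labels`.
#' @return list with `proteins` (numeric matrix, proteins x samples),
#'   `samples` (sample sheet with `cohort` set), and `truth`.
#' @examples
#' cfg <- sim_config(seed = 11, n_proteins = 100, n_per_group = 5,
#'                   group_labels = c("good", "poor"))
#' sim <- simulate_serum_cohorts(cfg)
#' dim(sim$proteins)
#' @export
simulate_serum_cohorts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (length(cfg$group_labels) != 2L) {
    stop_config("simulate_serum_cohorts needs exactly 2 group labels")
  }
  with_seed(cfg$seed, {
    prot <- protein_ids(cfg$n_proteins)
    n_disc <- floor(cfg$frac_discriminating * cfg$n_proteins)
    disc <- if (n_disc > 0) sort(sample(prot, n_disc)) else character(0)
    effects <- stats::setNames(rep(0, cfg$n_proteins), prot)
    effects[disc] <- cfg$effect_log2

    mu_prot <- stats::rnorm(cfg$n_proteins, mean = log(1e6), sd = 1.5)
    sdl <- sdlog_from_cv(cfg$cv)

    groups <- rep(cfg$group_labels, each = cfg$n_per_group)
    reps <- rep(seq_len(cfg$n_per_group), times = 2L)
    sample_id <- paste0(gsub("[^A-Za-z0-9.]+", ".", groups), "_s", reps)

    mat <- matrix(NA_real_, cfg$n_proteins, length(sample_id),
                  dimnames = list(prot, sample_id))
    for (j in seq_along(sample_id)) {
      shift <- if (groups[j] == cfg$group_labels[1]) 0 else effects * log(2)
      mat[, j] <- exp(mu_prot + shift + stats::rnorm(cfg$n_proteins, sd = sdl))
    }
    samples <- data.frame(
      sample_id = sample_id,
      group = groups,
      cohort = groups,
      replicate = reps,
      dfi_days = NA_integer_,
      stringsAsFactors = FALSE
    )
    list(proteins = mat, samples = samples,
         truth = new_sim_truth(disc, effects, cfg))
  })
}

#' Simulate 4PL dose-response viability readouts
#'
#' Viability at dose d is
#' `lower + (upper - lower) / (1 + (d / ic50)^hill)` plus Gaussian noise,
#' truncated at 0 (absorbance cannot be negative). At d = 0 the curve
#' equals `upper`; at d = ic50 it equals the midpoint `(lower + upper) / 2`.
#'
#' @param ic50 inflection concentration (uM), > 0.
#' @param hill hill slope (> 0 for a decreasing curve).
#' @param lower,upper asymptotes as fractions of control; `upper > lower`.
#' @param doses nonnegative concentrations (uM); the study's MTS design
#'   used 0, 0.5, 1, 2.5, 4, 6, 8 and 10 uM.
#' @param noise_sd Gaussian noise standard deviation (0 = exact curve).
#' @param seed integer seed (used only when `noise_sd > 0`).
#' @param n_replicates replicate wells per dose.
#' @return data.frame with columns `dose`, `replicate`, `viability`.
#' @examples
#' simulate_dose_response(5.62, 1, 0, 1, doses = c(0, 5.62, 10), noise_sd = 0)
#' @export
simulate_dose_response <- function(ic50, hill, lower, upper,
                                   doses = c(0, 0.5, 1, 2.5, 4, 6, 8, 10),
                                   noise_sd = 0, seed = 1L,
                                   n_replicates = 1L) {
  if (ic50 <= 0) stop_config("ic50 must be > 0")
  if (any(doses < 0)) stop_config("doses must be nonnegative")
  if (upper <= lower) stop_config("upper must exceed lower")
  if (noise_sd < 0) stop_config("noise_sd must be >= 0")
  d <- rep(doses, each = n_replicates)
  reps <- rep(seq_len(n_replicates), times = length(doses))
  v <- four_pl(d, ic50 = ic50, hill = hill, lower = lower, upper = upper)
  if (noise_sd > 0) {
    v <- with_seed(seed, v + stats::rnorm(length(v), sd = noise_sd))
  }
  data.frame(dose = d, replicate = reps, viability = pmax(v, 0))
}

#' Simulate an exponential growth record
#'
#' Inverse of the generation-time formula: the cell count after `h_elapsed`
#' hours of growth with doubling time `t_gen` is
#' `c2 = c1 * 2^(h_elapsed / t_gen)`. [generation_time()] recovers `t_gen`
#' from the record.
#'
#' @param h_elapsed hours between plating and counting (> 0).
#' @param c1 cells at plating (> 0).
#' @param t_gen doubling time in hours (> 0).
#' @return list with `h_elapsed`, `c1`, `c2`, `t_gen`.
#' @examples
#' simulate_growth(48, 1e5, 27.2)
#' @export
simulate_growth <- function(h_elapsed, c1, t_gen) {
  if (h_elapsed <= 0 || c1 <= 0 || t_gen <= 0) {
    stop_config("h_elapsed, c1 and t_gen must all be > 0")
  }
  list(h_elapsed = h_elapsed, c1 = c1,
       c2 = c1 * 2^(h_elapsed / t_gen), t_gen = t_gen)
}
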