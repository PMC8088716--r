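#' All cross-replicate abundance ratios
#'
#' Forms the full Cartesian product of ratios a/b between the observed
#' replicate abundances of two groups, in lexicographic (index_a, index_b)
#' order. Absent (`NA`) and nonpositive values contribute no ratio: a
#' replicate pair is only usable when both members were observed, and
#' imputation would manufacture signal.
#'
#' @param values_a,values_b numeric replicate abundances (may contain `NA`).
#' @return numeric vector of length `|A| * |B|` after dropping unusable
#'   values, or `NULL` when either side has no usable value (the peptide is
#'   flagged unusable upstream rather than raising an error).
#' @examples
#' ratio_combinations(c(2, 8), c(1, 4)) # 2.0 0.5 8.0 2.0
#' @export
ratio_combinations <- function(values_a, values_b) {
  a <- values_a[!is.na(values_a) & values_a > 0]
  b <- values_b[!is.na(values_b) & values_b > 0]
  if (length(a) == 0L || length(b) == 0L) return(NULL)
  # lexicographic in (index_a, index_b): a1/b1, a1/b2, ..., a2/b1, ...
  as.vector(t(outer(a, b, `/`)))
}

#' Geometric median of positive scalars
#'
#' The geometric median of positive scalars is the median in log space:
#' for vectors the geometric median is the L1-minimizing point, and in one
#' dimension that is the ordinary median, applied here to log-ratios. An
#' even count resolves to the arithmetic mean of the two central log
#' values, i.e. the geometric mean of the two central values.
#'
#' @param xs positive numeric vector.
#' @return positive scalar, invariant to the order of `xs`.
#' @examples
#' geometric_median_scalar(c(2, 0.5, 8, 2)) # 2
#' geometric_median_scalar(c(2, 8)) # 4
#' @export
geometric_median_scalar <- function(xs) {
  if (length(xs) == 0L || any(is.na(xs)) || any(xs <= 0)) {
    stop_data("geometric_median_scalar needs a nonempty vector of positive values")
  }
  exp(stats::median(log(xs)))
}

group_columns <- function(sheet, group) {
  ids <- sheet$sample_id[sheet$group == group]
  if (length(ids) == 0L) stop_config("unknown or empty group label: ", group)
  ids
}

peptide_matrix <- function(tbl) {
  if (!all(c("peptide_id", "protein_id") %in% names(tbl)[1:2])) {
    stop_data("peptide table must start with peptide_id and protein_id columns")
  }
  m <- as.matrix(tbl[, -(1:2), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- tbl$peptide_id
  m
}

#' Protein fold change by nested geometric medians
#'
#' Implements the study's fold-change definition: each peptide's group
#' ratio is the geometric median of all combinations of ratios between the
#' group-A and group-B replicates, and the protein fold change is the
#' geometric median of its peptide group ratios. Peptides with no usable
#' ratio pair are excluded and counted.
#'
#' @param tbl peptide table (data.frame: `peptide_id`, `protein_id`, sample
#'   columns).
#' @param sheet sample sheet with `sample_id` and `group` columns.
#' @param group_a,group_b group labels (fold change is A over B).
#' @param protein_id the protein to quantify.
#' @return list with `protein_id`, `fold_change`, `n_peptides_used`,
#'   `peptide_ratios`, or `NULL` (with a warning) when no peptide yields a
#'   usable ratio.
#' @examples
#' sim <- simulate_peptide_table(sim_config(seed = 1, n_proteins = 5,
#'   group_labels = c("A", "B")))
#' protein_fold_change(sim$peptides, sim$samples, "A", "B", "PROT00001")
#' @export
protein_fold_change <- function(tbl, sheet, group_a, group_b, protein_id) {
  cols_a <- group_columns(sheet, group_a)
  cols_b <- group_columns(sheet, group_b)
  sub <- tbl[tbl$protein_id == protein_id, , drop = FALSE]
  if (nrow(sub) == 0L) stop_data("protein not present in table: ", protein_id)
  m <- peptide_matrix(sub)
  ratios <- vapply(seq_len(nrow(m)), function(i) {
    r <- ratio_combinations(m[i, cols_a], m[i, cols_b])
    if (is.null(r)) NA_real_ else geometric_median_scalar(r)
  }, numeric(1))
  used <- !is.na(ratios)
  if (!any(used)) {
    warning("protein ", protein_id, " has no peptide with a usable ratio pair")
    return(NULL)
  }
  list(
    protein_id = protein_id,
    fold_change = geometric_median_scalar(ratios[used]),
    n_peptides_used = sum(used),
    peptide_ratios = unname(ratios[used])
  )
}

#' Fold-change table for all quantifiable proteins
#'
#' Applies [protein_fold_change()] to every protein with at least one
#' usable peptide. Proteins detected in exactly one group get an `Inf`
#' (A only) or `0` (B only) sentinel with an explanatory flag rather than a
#' fold change; proteins with no observations in either group are dropped.
#'
#' @inheritParams protein_fold_change
#' @return data.frame with `protein_id`, `fold_change`, `n_peptides_used`,
#'   `flag` (`"ok"`, `"only_group_a"`, `"only_group_b"`), ordered by
#'   `protein_id`.
#' @examples
#' sim <- simulate_peptide_table(sim_config(seed = 1, n_proteins = 10,
#'   group_labels = c("A", "B")))
#' head(fold_change_table(sim$peptides, sim$samples, "A", "B"))
#' @export
fold_change_table <- function(tbl, sheet, group_a, group_b) {
  cols_a <- group_columns(sheet, group_a)
  cols_b <- group_columns(sheet, group_b)
  m <- peptide_matrix(tbl)
  prots <- sort(unique(tbl$protein_id))
  rows <- lapply(prots, function(p) {
    idx <- which(tbl$protein_id == p)
    ratios <- rep(NA_real_, length(idx))
    seen_a <- FALSE
    seen_b <- FALSE
    for (k in seq_along(idx)) {
      va <- m[idx[k], cols_a]
      vb <- m[idx[k], cols_b]
      if (any(!is.na(va) & va > 0)) seen_a <- TRUE
      if (any(!is.na(vb) & vb > 0)) seen_b <- TRUE
      r <- ratio_combinations(va, vb)
      if (!is.null(r)) ratios[k] <- geometric_median_scalar(r)
    }
    used <- !is.na(ratios)
    if (any(used)) {
      data.frame(protein_id = p,
                 fold_change = geometric_median_scalar(ratios[used]),
                 n_peptides_used = sum(used), flag = "ok",
                 stringsAsFactors = FALSE)
    } else if (seen_a && !seen_b) {
      data.frame(protein_id = p, fold_change = Inf, n_peptides_used = 0L,
                 flag = "only_group_a", stringsAsFactors = FALSE)
    } else if (seen_b && !seen_a) {
      data.frame(protein_id = p, fold_change = 0, n_peptides_used = 0L,
                 flag = "only_group_b", stringsAsFactors = FALSE)
    } else {
      NULL
    }
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    warning("no protein had a usable replicate ratio pair")
    return(data.frame(protein_id = character(0), fold_change = numeric(0),
                      n_peptides_used = integer(0), flag = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Filter proteins by fold-change threshold
#'
#' Keeps proteins whose quantified fold change is at least `min_fold`
#' (direction `"over"`) or at most `1 / min_fold` (direction `"under"`).
#' Only `"ok"`-flagged rows are compared; single-group sentinels are
#' detection events, not fold changes, and are handled by
#' [detection_sets()].
#'
#' @param results data.frame from [fold_change_table()].
#' @param min_fold positive threshold (the study used 100).
#' @param direction `"over"` or `"under"`.
#' @return character vector of protein ids, sorted.
#' @examples
#' res <- data.frame(protein_id = c("A", "B", "C"),
#'                   fold_change = c(150, 99, 0.005),
#'                   n_peptides_used = 1L, flag = "ok")
#' threshold_filter(res, 100, "over")
#' @export
threshold_filter <- function(results, min_fold, direction = c("over", "under")) {
  direction <- match.arg(direction)
  if (min_fold <= 0) stop_config("min_fold must be > 0")
  ok <- results[results$flag == "ok", , drop = FALSE]
  keep <- if (direction == "over") {
    ok$fold_change >= min_fold
  } else {
    ok$fold_change <= 1 / min_fold
  }
  sort(ok$protein_id[keep])
}
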