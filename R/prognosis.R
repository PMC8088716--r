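#' Train a serum-exosome prognosis signature
#'
#' Formalizes the study's prognosis score as a linear model over
#' discriminating proteins: features are selected by t-test p-value, each
#' feature's weight is its t-score oriented so that positive weights mark
#' proteins negatively correlated with good outcome (more abundant in poor
#' responders), abundances are standardized with training-set means and
#' SDs, and a sample's net score is the weighted sum of its standardized
#' abundances. Lower net score means better predicted prognosis. The
#' decision boundary is the midpoint of the two training cohorts' mean net
#' scores rather than a fixed zero, mirroring a data-driven decision line.
#'
#' The underlying study displays the score's construction only graphically;
#' this linear formalization is the minimal model consistent with the
#' plotted sign-split contribution axes and the lower-is-better convention.
#'
#' @param tbl numeric protein x sample matrix (raw abundances; total-sum
#'   scaling is applied internally when `normalize = TRUE`).
#' @param sheet sample sheet with `sample_id` and `cohort`.
#' @param good_label,poor_label cohort labels.
#' @param max_features cap on selected features by decreasing |t|
#'   (default `Inf`, i.e. all below the p cutoff).
#' @param p_cutoff feature-selection p-value threshold (default 0.05).
#' @param normalize apply [normalize_columns()] before training and require
#'   it again at scoring time (default TRUE).
#' @param var_equal pooled-variance t (default) or Welch.
#' @return object of class `signature_model`: `selected_features`, `weight`
#'   (named; positive = poor-associated), `standardization` (`mean`, `sd`
#'   per feature), `boundary`, `orientation` (`"lower_is_good"`),
#'   `good_label`, `poor_label`, `normalize`.
#' @examples
#' sim <- simulate_serum_cohorts(sim_config(seed = 11, n_proteins = 100,
#'   n_per_group = 5, group_labels = c("good", "poor")))
#' model <- train_signature(sim$proteins, sim$samples, "good", "poor")
#' length(model$selected_features)
#' @export
train_signature <- function(tbl, sheet, good_label, poor_label,
                            max_features = Inf, p_cutoff = 0.05,
                            normalize = TRUE, var_equal = TRUE) {
  m <- as_protein_matrix(tbl)
  if (normalize) m <- normalize_columns(m)
  scores <- feature_t_scores(m, sheet, good_label, poor_label,
                             normalize = FALSE, var_equal = var_equal)
  good_cols <- sheet$sample_id[!is.na(sheet$cohort) & sheet$cohort == good_label]
  poor_cols <- sheet$sample_id[!is.na(sheet$cohort) & sheet$cohort == poor_label]

  sel <- scores[is.finite(scores$t_score) & scores$p_value < p_cutoff, ]
  train_sd <- apply(m[sel$protein_id, c(good_cols, poor_cols), drop = FALSE],
                    1, stats::sd)
  sel <- sel[train_sd[sel$protein_id] > 0, ]
  if (nrow(sel) == 0L) {
    stop_data("no signature: no feature passed p < ", p_cutoff,
              "; relax p_cutoff or provide more discriminating data")
  }
  if (is.finite(max_features) && nrow(sel) > max_features) {
    sel <- sel[order(-abs(sel$t_score), sel$protein_id), ][seq_len(max_features), ]
  }
  feats <- sel$protein_id
  # positive weight = negatively correlated with good outcome (high in poor)
  weight <- stats::setNames(-sel$t_score, feats)
  train <- m[feats, c(good_cols, poor_cols), drop = FALSE]
  std <- list(mean = rowMeans(train), sd = apply(train, 1, stats::sd))

  model <- structure(
    list(selected_features = feats, weight = weight, standardization = std,
         boundary = NA_real_, orientation = "lower_is_good",
         good_label = good_label, poor_label = poor_label,
         normalize = normalize),
    class = "signature_model"
  )
  net <- function(cols) {
    vapply(cols,
           function(s) score_sample(model, m[, s], prenormalized = TRUE)$net_score,
           numeric(1))
  }
  model$boundary <- (mean(net(good_cols)) + mean(net(poor_cols))) / 2
  model
}

#' @export
print.signature_model <- function(x, ...) {
  cat("Prognosis signature model\n")
  cat("  features:", length(x$selected_features),
      " boundary:", format(x$boundary, digits = 4),
      " (net score < boundary =>", x$good_label, ")\n")
  invisible(x)
}

#' Score one sample against a trained signature
#'
#' Decomposes a sample into the two plotted contribution axes: the sum of
#' weighted standardized abundances over features negatively correlated
#' with good outcome (positive weights) and over features positively
#' correlated with good outcome (negative weights, sign flipped). The net
#' score is their difference; samples scoring below the boundary are called
#' good, and an exact tie is called poor (the conservative clinical
#' default).
#'
#' @param model a [train_signature()] model.
#' @param sample named numeric vector: one sample's full abundance column
#'   (raw when the model was trained with `normalize = TRUE`; the column is
#'   rescaled by its own total, which involves no training information).
#' @param prenormalized set TRUE when `sample` is already total-sum scaled.
#' @return list of class `score_decomposition`: `contrib_negative`,
#'   `contrib_positive`, `net_score`, `predicted`.
#' @export
score_sample <- function(model, sample, prenormalized = FALSE) {
  stopifnot(inherits(model, "signature_model"))
  feats <- model$selected_features
  if (!all(feats %in% names(sample))) {
    stop_data("sample is missing selected feature(s): ",
              paste(setdiff(feats, names(sample)), collapse = ", "))
  }
  x <- sample
  if (model$normalize && !prenormalized) {
    tot <- sum(x, na.rm = TRUE)
    if (!(tot > 0)) stop_data("sample total must be positive to normalize")
    x <- x / tot
  }
  x <- x[feats]
  if (any(is.na(x))) {
    stop_data("missing abundance for feature(s): ",
              paste(feats[is.na(x)], collapse = ", "))
  }
  z <- (x - model$standardization$mean) / model$standardization$sd
  contrib <- model$weight * z
  neg_assoc <- model$weight > 0   # negatively correlated with good outcome
  contrib_negative <- sum(contrib[neg_assoc])
  contrib_positive <- sum(-contrib[!neg_assoc])
  net <- contrib_negative - contrib_positive
  structure(
    list(contrib_negative = contrib_negative,
         contrib_positive = contrib_positive,
         net_score = net,
         predicted = if (is.na(model$boundary)) NA_character_
                     else if (net < model$boundary) model$good_label
                     else model$poor_label),
    class = "score_decomposition"
  )
}

#' Leave-one-out accuracy of the prognosis score
#'
#' Holds out each sample in turn and retrains the entire signature --
#' normalization statistics, feature selection, standardization and the
#' decision boundary -- on the remaining samples before scoring the
#' held-out column, so no information leaks across folds. A fold in which
#' no feature passes selection counts its sample as misclassified and
#' flags it.
#'
#' @inheritParams train_signature
#' @return list with `accuracy` (fraction correct) and `decompositions`
#'   (data.frame: `sample_id`, `contrib_negative`, `contrib_positive`,
#'   `net_score`, `predicted`, `true`, `fold_failed`).
#' @examples
#' sim <- simulate_serum_cohorts(sim_config(seed = 11, n_proteins = 500,
#'   frac_discriminating = 0.04, effect_log2 = 2, cv = 0.2,
#'   n_per_group = 5, group_labels = c("good", "poor")))
#' loo_accuracy(sim$proteins, sim$samples, "good", "poor")$accuracy
#' @export
loo_accuracy <- function(tbl, sheet, good_label, poor_label,
                         max_features = Inf, p_cutoff = 0.05,
                         normalize = TRUE, var_equal = TRUE) {
  m <- as_protein_matrix(tbl)
  keep <- sheet[!is.na(sheet$cohort) &
                  sheet$cohort %in% c(good_label, poor_label), , drop = FALSE]
  if (nrow(keep) < 4L) stop_config(">= 2 samples per cohort required")
  rows <- lapply(seq_len(nrow(keep)), function(i) {
    held <- keep$sample_id[i]
    train_sheet <- keep[-i, , drop = FALSE]
    train_m <- m[, train_sheet$sample_id, drop = FALSE]
    dec <- tryCatch({
      fit <- train_signature(train_m, train_sheet, good_label, poor_label,
                             max_features = max_features,
                             p_cutoff = p_cutoff, normalize = normalize,
                             var_equal = var_equal)
      c(score_sample(fit, m[, held]), fold_failed = FALSE)
    }, exosig_data_error = function(e) {
      list(contrib_negative = NA_real_, contrib_positive = NA_real_,
           net_score = NA_real_, predicted = NA_character_,
           fold_failed = TRUE)
    })
    data.frame(sample_id = held,
               contrib_negative = dec$contrib_negative,
               contrib_positive = dec$contrib_positive,
               net_score = dec$net_score,
               predicted = if (is.null(dec$predicted)) NA_character_ else dec$predicted,
               true = keep$cohort[i],
               fold_failed = dec$fold_failed,
               stringsAsFactors = FALSE)
  })
  dec <- do.call(rbind, rows)
  correct <- !is.na(dec$predicted) & dec$predicted == dec$true
  list(accuracy = mean(correct), decompositions = dec)
}
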