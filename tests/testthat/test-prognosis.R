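sep_matrix <- function() {
  # one perfectly separating protein plus a flat one (so total-sum scaling
  # stays meaningful), good: 10,11,12 vs poor: 1,2,3
  samples <- paste0("s", 1:6)
  m <- matrix(c(10, 11, 12, 1, 2, 3,
                5, 5, 5, 5, 5, 5), 2, 6, byrow = TRUE,
              dimnames = list(c("Psep", "Pflat"), samples))
  sheet <- make_sheet(samples, rep(c("good", "poor"), each = 3))
  list(m = m, sheet = sheet)
}

test_that("a perfectly separating feature is selected and classifies training data", {
  fx <- sep_matrix()
  model <- train_signature(fx$m, fx$sheet, "good", "poor", normalize = FALSE)
  expect_equal(model$selected_features, "Psep")
  expect_lt(model$weight[["Psep"]], 0)  # abundant in good => good-associated
  preds <- vapply(colnames(fx$m), function(s)
    score_sample(model, fx$m[, s])$predicted, character(1))
  expect_equal(unname(preds), fx$sheet$cohort)
})

test_that("net score decomposes exactly into the two contribution axes", {
  sim <- simulate_serum_cohorts(serum_cfg(seed = 11, effect_log2 = 2))
  model <- train_signature(sim$proteins, sim$samples, "good", "poor")
  for (s in colnames(sim$proteins)) {
    d <- score_sample(model, sim$proteins[, s])
    expect_identical(d$net_score, d$contrib_negative - d$contrib_positive)
  }
})

test_that("swapping cohort labels negates weights and net scores and flips calls", {
  sim <- simulate_serum_cohorts(serum_cfg(seed = 8, effect_log2 = 1.5))
  m1 <- train_signature(sim$proteins, sim$samples, "good", "poor")
  m2 <- train_signature(sim$proteins, sim$samples, "poor", "good")
  expect_setequal(m1$selected_features, m2$selected_features)
  f <- m1$selected_features
  expect_equal(unname(m1$weight[f]), -unname(m2$weight[f]))
  expect_equal(m1$boundary, -m2$boundary)
  for (s in sample(colnames(sim$proteins), 4)) {
    d1 <- score_sample(m1, sim$proteins[, s])
    d2 <- score_sample(m2, sim$proteins[, s])
    expect_equal(d1$net_score, -d2$net_score)
    # the sample lands on the opposite side of the (negated) boundary, so
    # the emitted clinical label is unchanged
    expect_equal(d1$predicted, d2$predicted)
  }
})

test_that("raising a poor-associated feature never lowers the net score", {
  fx <- sep_matrix()
  # make Pflat poor-associated with noise so both signs appear
  set.seed(2)
  fx$m["Pflat", ] <- c(1, 2, 1.5, 8, 9, 10) # abundant in poor
  model <- train_signature(fx$m, fx$sheet, "good", "poor",
                           normalize = FALSE, p_cutoff = 0.2)
  poor_feat <- names(which(model$weight > 0))
  expect_true(length(poor_feat) >= 1)
  s <- fx$m[, "s1"]
  base <- score_sample(model, s)$net_score
  for (bump in c(0.5, 2, 10)) {
    s2 <- s
    s2[poor_feat[1]] <- s2[poor_feat[1]] + bump
    expect_gte(score_sample(model, s2)$net_score, base)
  }
})

test_that("an exact boundary tie is called poor and missing features are named", {
  fx <- sep_matrix()
  model <- train_signature(fx$m, fx$sheet, "good", "poor", normalize = FALSE)
  # invert the standardized score to land exactly on the boundary
  mu <- model$standardization$mean[["Psep"]]
  sd_ <- model$standardization$sd[["Psep"]]
  w <- model$weight[["Psep"]]
  x_tie <- mu + sd_ * model$boundary / w
  tie <- score_sample(model, c(Psep = x_tie, Pflat = 5))
  expect_equal(tie$net_score, model$boundary, tolerance = 1e-12)
  expect_equal(tie$predicted, "poor")
  expect_error(score_sample(model, c(Pflat = 5)), "Psep",
               class = "exosig_data_error")
})

test_that("no feature passing selection raises a 'no signature' data error", {
  sim <- simulate_serum_cohorts(serum_cfg(seed = 3, effect_log2 = 0,
                                          n_proteins = 100))
  expect_error(
    train_signature(sim$proteins, sim$samples, "good", "poor",
                    p_cutoff = 1e-6),
    "no signature", class = "exosig_data_error")
})

test_that("duplicating every training sample preserves selection signs and calls", {
  sim <- simulate_serum_cohorts(serum_cfg(seed = 21, effect_log2 = 1.5,
                                          n_proteins = 200))
  m <- sim$proteins
  m2 <- cbind(m, m)
  colnames(m2) <- c(colnames(m), paste0(colnames(m), "_dup"))
  sheet2 <- rbind(sim$samples,
                  transform(sim$samples, sample_id = paste0(sample_id, "_dup")))
  a <- train_signature(m, sim$samples, "good", "poor")
  b <- train_signature(m2, sheet2, "good", "poor")
  # duplication shrinks every p-value, so the original selection survives
  expect_true(all(a$selected_features %in% b$selected_features))
  common <- a$selected_features
  expect_equal(sign(a$weight[common]), sign(b$weight[common]))
  pa <- vapply(colnames(m), function(s) score_sample(a, m[, s])$predicted,
               character(1))
  pb <- vapply(colnames(m), function(s) score_sample(b, m[, s])$predicted,
               character(1))
  expect_equal(pa, pb)
})

test_that("leave-one-out separates strongly shifted cohorts perfectly", {
  sim <- simulate_serum_cohorts(serum_cfg(seed = 11, effect_log2 = 2))
  res <- loo_accuracy(sim$proteins, sim$samples, "good", "poor")
  expect_equal(res$accuracy, 1)
  expect_false(any(res$decompositions$fold_failed))
  expect_equal(res$decompositions$net_score,
               res$decompositions$contrib_negative -
                 res$decompositions$contrib_positive)
})

test_that("null cohorts never beat chance under leave-one-out (no leakage)", {
  accs <- vapply(1:10, function(s) {
    sim <- simulate_serum_cohorts(serum_cfg(seed = s, effect_log2 = 0))
    loo_accuracy(sim$proteins, sim$samples, "good", "poor")$accuracy
  }, numeric(1))
  se <- stats::sd(accs) / sqrt(length(accs))
  # leakage across folds would push accuracy above chance; the estimator
  # itself sits at or below 0.5 (leave-one-out anti-learning bias)
  expect_lte(mean(accs), 0.5 + 2 * se)
})

test_that("folds without selectable features count as misclassified and are flagged", {
  sim <- simulate_serum_cohorts(serum_cfg(seed = 3, effect_log2 = 0,
                                          n_proteins = 20))
  res <- loo_accuracy(sim$proteins, sim$samples, "good", "poor",
                      p_cutoff = 1e-9)
  expect_true(all(res$decompositions$fold_failed))
  expect_equal(res$accuracy, 0)
})
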