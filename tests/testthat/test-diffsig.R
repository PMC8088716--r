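prot_mat <- function(vals, n_prot, samples) {
  matrix(vals, n_prot, length(samples),
         dimnames = list(sprintf("P%02d", seq_len(n_prot)), samples))
}

test_that("normalize_columns is total-sum scaling", {
  m <- prot_mat(c(1, 1, 2), 3, "s1")
  n <- normalize_columns(m)
  expect_equal(unname(n[, 1]), c(0.25, 0.25, 0.5))
  expect_equal(normalize_columns(n), n)           # idempotent
  set.seed(1)
  big <- prot_mat(stats::runif(60), 10, paste0("s", 1:6))
  expect_equal(unname(colSums(normalize_columns(big))), rep(1, 6),
               tolerance = 1e-12)
  zero <- prot_mat(c(1, 0, 1, 0), 2, c("ok", "bad"))
  zero[, "bad"] <- 0
  expect_error(normalize_columns(zero), "bad", class = "exosig_data_error")
})

test_that("feature t-scores match the pooled-variance formula and t.test", {
  samples <- paste0("s", 1:6)
  sheet <- make_sheet(samples, rep(c("c1", "c2"), each = 3))
  m <- prot_mat(c(1, 2, 3, 4, 5, 6), 1, samples)  # c1: 1,2,3; c2: 4,5,6
  sc <- feature_t_scores(m, sheet, "c1", "c2", normalize = FALSE)
  expect_equal(sc$t_score, -3.674235, tolerance = 1e-6)
  expect_equal(sc$p_value, 0.02131164, tolerance = 1e-6)

  # identical cohorts -> t = 0, p = 1
  m2 <- prot_mat(rep(c(1, 2, 3), 2), 1, samples)
  m2[1, ] <- c(1, 2, 3, 1, 2, 3)
  sc2 <- feature_t_scores(m2, sheet, "c1", "c2", normalize = FALSE)
  expect_equal(sc2$t_score, 0)
  expect_equal(sc2$p_value, 1)

  # swapping cohorts negates t, keeps p
  set.seed(5)
  m3 <- prot_mat(exp(stats::rnorm(120)), 20, samples)
  a <- feature_t_scores(m3, sheet, "c1", "c2", normalize = FALSE)
  b <- feature_t_scores(m3, sheet, "c2", "c1", normalize = FALSE)
  b <- b[match(a$protein_id, b$protein_id), ]
  expect_equal(a$t_score, -b$t_score)
  expect_equal(a$p_value, b$p_value)

  # cross-check both variants against stats::t.test row by row
  for (var_equal in c(TRUE, FALSE)) {
    sc4 <- feature_t_scores(m3, sheet, "c1", "c2", normalize = FALSE,
                            var_equal = var_equal)
    for (p in sample(rownames(m3), 5)) {
      tt <- stats::t.test(m3[p, 1:3], m3[p, 4:6], var.equal = var_equal)
      i <- which(sc4$protein_id == p)
      expect_equal(sc4$t_score[i], unname(tt$statistic), tolerance = 1e-10)
      expect_equal(sc4$p_value[i], tt$p.value, tolerance = 1e-10)
    }
  }
})

test_that("degenerate zero-variance proteins get sentinel t-scores", {
  samples <- paste0("s", 1:4)
  sheet <- make_sheet(samples, rep(c("c1", "c2"), each = 2))
  m <- prot_mat(0, 2, samples)
  m["P01", ] <- c(5, 5, 5, 5)   # equal means, no variance
  m["P02", ] <- c(7, 7, 2, 2)   # unequal means, no variance
  sc <- feature_t_scores(m, sheet, "c1", "c2", normalize = FALSE)
  expect_equal(sc$t_score[sc$protein_id == "P01"], 0)
  expect_equal(sc$p_value[sc$protein_id == "P01"], 1)
  expect_equal(sc$t_score[sc$protein_id == "P02"], Inf)
  expect_equal(sc$p_value[sc$protein_id == "P02"], 0)
})

test_that("t-score ordering is total and deterministic", {
  samples <- paste0("s", 1:6)
  sheet <- make_sheet(samples, rep(c("c1", "c2"), each = 3))
  m <- prot_mat(rep(c(1, 2, 3, 4, 5, 6), each = 3), 3, samples)
  sc <- feature_t_scores(m, sheet, "c1", "c2", normalize = FALSE)
  # all three rows tie (identical t); order falls back to protein_id
  expect_equal(sc$protein_id, sort(sc$protein_id))
  expect_false(is.unsorted(rev(sc$t_score)))
})

test_that("heatmap matrix is log2 relative to the reference-cohort mean", {
  samples <- paste0("s", 1:4)
  sheet <- make_sheet(samples, rep(c("ref", "other"), each = 2))
  m <- prot_mat(0, 2, samples)
  m["P01", ] <- c(2, 2, 4, 2)    # sample s3 doubles the reference mean
  m["P02", ] <- c(1, 3, 2, 5)
  sc <- feature_t_scores(m, sheet, "ref", "other", normalize = FALSE)
  hm <- heatmap_matrix(m, sheet, "ref", sc, normalize = FALSE)
  expect_equal(hm$values["P01", "s3"], 1, tolerance = 1e-6)
  expect_equal(hm$values["P01", "s4"], 0, tolerance = 1e-6)
  expect_equal(hm$values["P02", "s3"], 0, tolerance = 1e-6)
  expect_identical(rownames(hm$values), sc$protein_id)
  # the reference cohort's mean profile maps to the zero vector
  ref_mean <- rowMeans(m[, hm$reference_columns])
  eps <- 1e-9 * mean(m)
  expect_equal(unname(log2((ref_mean + eps) / (ref_mean + eps))), c(0, 0))
  expect_equal(unname(rowMeans(2^hm$values[, hm$reference_columns])), c(1, 1),
               tolerance = 1e-6)
})

test_that("detection sets partition the union for 2 and 3 groups", {
  ds <- detection_sets(list(A = c("1", "2"), B = c("2", "3"), C = "2"))
  expect_equal(ds$regions$A, "1")
  expect_equal(ds$regions$B, "3")
  expect_equal(ds$regions$C, character(0))
  expect_equal(ds$regions$`A&B&C`, "2")
  expect_equal(sum(ds$counts), length(ds$universe))

  same <- detection_sets(list(A = c("x", "y"), B = c("x", "y"), C = c("x", "y")))
  expect_equal(unname(same$counts["A&B&C"]), 2L)
  expect_equal(sum(same$counts), 2L)

  disj <- detection_sets(list(A = "1", B = "2", C = "3"))
  expect_equal(unname(disj$counts[c("A", "B", "C")]), c(1L, 1L, 1L))
  expect_equal(sum(disj$counts), 3L)

  two <- detection_sets(list(A = c("1", "2"), B = c("2", "3")))
  expect_equal(unname(two$counts[c("A", "B", "A&B")]), c(1L, 1L, 1L))

  expect_error(detection_sets(list(A = "1", B = "1", C = "1", D = "1")),
               class = "exosig_config_error")
  expect_error(detection_sets(list("1", "2")), class = "exosig_config_error")

  # property: random 3-way sets always partition their union
  set.seed(11)
  for (i in 1:20) {
    sets <- lapply(1:3, function(k) sample(letters, sample(0:15, 1)))
    names(sets) <- c("g1", "g2", "g3")
    ds <- detection_sets(sets)
    expect_equal(sum(ds$counts), length(unique(unlist(sets))))
    expect_setequal(unlist(ds$regions), unique(unlist(sets)))
  }
})

test_that("ortholog similarity retention is strictly greater than 99", {
  rows <- data.frame(protein_id = c("P1", "P2", "P3"),
                     percent_similarity = c(99.5, 98, 100))
  expect_equal(ortholog_similarity_filter(rows), c("P1", "P3"))
  expect_equal(ortholog_similarity_filter(
    data.frame(protein_id = "P4", percent_similarity = 99)), character(0))
  expect_equal(ortholog_similarity_filter(
    data.frame(protein_id = character(0), percent_similarity = numeric(0))),
    character(0))
  expect_error(ortholog_similarity_filter(
    data.frame(protein_id = "P", percent_similarity = 101)),
    class = "exosig_data_error")
})

test_that("enrichment odds ratio and hypergeometric tail match hand computation", {
  coll <- list(sets = list(S = as.character(1:5)),
               background = as.character(1:20))
  res <- enrichment_odds_ratios(as.character(c(1, 2, 3, 10, 11, 12)), coll)
  expect_equal(res$odds_ratio, 6)
  expect_equal(res$p_value, 0.1313209, tolerance = 1e-6)
  # independent cross-check: one-sided Fisher p equals the hypergeometric tail
  ft <- stats::fisher.test(matrix(c(3, 3, 2, 12), 2), alternative = "greater")
  expect_equal(res$p_value, ft$p.value, tolerance = 1e-10)

  disjoint <- enrichment_odds_ratios(as.character(10:15), coll)
  expect_lt(disjoint$odds_ratio, 1)
  expect_gte(disjoint$p_value, 0.5)

  maximal <- enrichment_odds_ratios(as.character(1:5), coll)
  expect_gt(maximal$odds_ratio, 100)
  expect_equal(maximal$p_value, 1 / choose(20, 5), tolerance = 1e-10)

  expect_error(enrichment_odds_ratios(character(0), coll),
               class = "exosig_config_error")
  expect_error(enrichment_odds_ratios("99", coll), class = "exosig_data_error")
})

test_that("GMT round trip preserves sets and background", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc A\tg1\tg2\tg3",
               "setB\t-\tg2\tg4"), path)
  coll <- read_gmt(path)
  expect_equal(coll$sets$setA, c("g1", "g2", "g3"))
  expect_equal(coll$sets$setB, c("g2", "g4"))
  expect_setequal(coll$background, c("g1", "g2", "g3", "g4"))
  writeLines("broken\tonly-two-fields", path)
  expect_error(read_gmt(path), class = "exosig_data_error")
})
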