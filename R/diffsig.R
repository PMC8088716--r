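#' Total-sum column normalization
#'
#' Divides each sample column by its total so every column sums to 1
#' (total-sum scaling), the normalization applied to the serum exosome
#' abundances before statistical testing and heatmap display.
#'
#' @param tbl numeric protein x sample matrix with row and column names.
#' @return matrix of the same shape; each column sums to 1.
#' @examples
#' m <- matrix(c(1, 1, 2), 3, 1, dimnames = list(paste0("P", 1:3), "s1"))
#' normalize_columns(m)
#' @export
normalize_columns <- function(tbl) {
  tbl <- as_protein_matrix(tbl)
  if (any(tbl < 0, na.rm = TRUE)) stop_data("abundances must be nonnegative")
  tot <- colSums(tbl, na.rm = TRUE)
  bad <- which(!(tot > 0))
  if (length(bad)) {
    stop_data("column total is not positive for sample(s): ",
              paste(colnames(tbl)[bad], collapse = ", "))
  }
  sweep(tbl, 2, tot, `/`)
}

as_protein_matrix <- function(tbl) {
  m <- as.matrix(tbl)
  storage.mode(m) <- "double"
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop_data("protein table needs protein row names and sample column names")
  }
  if (anyDuplicated(rownames(m))) stop_data("duplicate protein ids")
  if (anyDuplicated(colnames(m))) stop_data("duplicate sample ids")
  m
}

# Row-wise two-sample t statistics over a matrix (pooled or Welch).
row_t_stats <- function(x1, x2, var_equal = TRUE) {
  n1 <- ncol(x1)
  n2 <- ncol(x2)
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  v1 <- apply(x1, 1, stats::var)
  v2 <- apply(x2, 1, stats::var)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- (m1 - m2) / se
  # degenerate rows: zero pooled variance
  zero_se <- !is.na(se) & se == 0
  t[zero_se & m1 == m2] <- 0
  t[zero_se & m1 > m2] <- Inf
  t[zero_se & m1 < m2] <- -Inf
  p <- ifelse(is.infinite(t), 0,
              2 * stats::pt(abs(t), df, lower.tail = FALSE))
  p[zero_se & m1 == m2] <- 1
  list(t = t, p = p, mean1 = m1, mean2 = m2, df = df)
}

#' Per-protein t-score feature ranking
#'
#' Two-sample t statistics (cohort1 minus cohort2) per protein with
#' two-sided p-values, the feature ranking behind the study's heatmap row
#' order. The default is the Student (pooled-variance) test matching a
#' Prism-style workflow; `var_equal = FALSE` switches to Welch.
#' Benjamini-Hochberg q-values are reported alongside raw p as an
#' extension: the displayed statistics threshold raw p, but a 5-vs-5
#' proteome-wide scan warrants a multiplicity-aware column.
#'
#' @param tbl numeric protein x sample matrix.
#' @param sheet sample sheet with `sample_id` and `cohort` columns.
#' @param cohort1,cohort2 cohort labels; the t sign follows
#'   cohort1 - cohort2.
#' @param normalize apply [normalize_columns()] first (default TRUE).
#' @param var_equal pooled variance (TRUE, default) or Welch (FALSE).
#' @return data.frame sorted by descending `t_score` (ties broken by
#'   `protein_id`) with columns `protein_id`, `t_score`, `p_value`,
#'   `q_value`, `mean_group1`, `mean_group2`, `direction` (`"positive"` if
#'   associated with cohort1).
#' @examples
#' sim <- simulate_serum_cohorts(sim_config(seed = 3, n_proteins = 50,
#'   n_per_group = 5, group_labels = c("good", "poor")))
#' head(feature_t_scores(sim$proteins, sim$samples, "good", "poor"))
#' @export
feature_t_scores <- function(tbl, sheet, cohort1, cohort2,
                             normalize = TRUE, var_equal = TRUE) {
  m <- as_protein_matrix(tbl)
  if (normalize) m <- normalize_columns(m)
  c1 <- sheet$sample_id[!is.na(sheet$cohort) & sheet$cohort == cohort1]
  c2 <- sheet$sample_id[!is.na(sheet$cohort) & sheet$cohort == cohort2]
  if (length(c1) < 2L || length(c2) < 2L) {
    stop_config("each cohort needs >= 2 samples")
  }
  st <- row_t_stats(m[, c1, drop = FALSE], m[, c2, drop = FALSE], var_equal)
  out <- data.frame(
    protein_id = rownames(m),
    t_score = unname(st$t),
    p_value = unname(st$p),
    q_value = unname(stats::p.adjust(st$p, method = "BH")),
    mean_group1 = unname(st$mean1),
    mean_group2 = unname(st$mean2),
    direction = ifelse(st$t >= 0, "positive", "negative"),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$t_score, out$protein_id), ]
  rownames(out) <- NULL
  out
}

#' Reference-relative log2 heatmap matrix
#'
#' Builds the matrix behind the study's serum heatmap: each cell is the
#' log2 ratio of a sample's normalized abundance to the mean of the
#' reference cohort's columns for that protein, with rows ordered by
#' descending t-score. A sample equal to the reference mean maps to 0.
#'
#' @param tbl numeric protein x sample matrix.
#' @param sheet sample sheet with `sample_id` and `cohort`.
#' @param reference_cohort cohort whose column mean anchors each row.
#' @param scores output of [feature_t_scores()] (supplies the row order).
#' @param eps pseudocount guarding log2 of zero cells; default 1e-9 of the
#'   normalized matrix mean, small enough not to distort nonzero entries.
#' @param normalize apply [normalize_columns()] first (default TRUE).
#' @return list of class `heatmap_matrix`: `values` (log2 matrix, rows in
#'   score order), `row_order`, `reference_columns`.
#' @export
heatmap_matrix <- function(tbl, sheet, reference_cohort, scores,
                           eps = NULL, normalize = TRUE) {
  m <- as_protein_matrix(tbl)
  if (normalize) m <- normalize_columns(m)
  ref <- sheet$sample_id[!is.na(sheet$cohort) & sheet$cohort == reference_cohort]
  if (length(ref) == 0L) stop_config("reference cohort is empty: ", reference_cohort)
  if (is.null(eps)) eps <- 1e-9 * mean(m)
  ref_mean <- rowMeans(m[, ref, drop = FALSE])
  vals <- log2(sweep(m + eps, 1, ref_mean + eps, `/`))
  ord <- scores$protein_id
  if (!setequal(ord, rownames(m))) {
    stop_data("scores and table cover different protein sets")
  }
  structure(
    list(values = vals[ord, , drop = FALSE],
         row_order = ord,
         reference_columns = ref),
    class = "heatmap_matrix"
  )
}

#' Venn detection regions for 2 or 3 groups
#'
#' Partitions the union of detected protein ids into the standard Venn
#' regions: unique to each group, each pairwise-only overlap, and the
#' all-shared core. Region names join the member group labels with `&`.
#'
#' @param presence named list (2 or 3 entries) of protein id vectors.
#' @return list of class `detection_sets` with `regions` (named list of id
#'   vectors) and `counts` (named integer vector); regions partition the
#'   union of all groups.
#' @examples
#' detection_sets(list(A = c("1", "2"), B = c("2", "3"), C = "2"))
#' @export
detection_sets <- function(presence) {
  k <- length(presence)
  if (k < 2L || k > 3L) {
    stop_config("detection_sets supports exactly 2 or 3 groups, got ", k)
  }
  labs <- names(presence)
  if (is.null(labs) || any(!nzchar(labs)) || anyDuplicated(labs)) {
    stop_config("presence must be a named list with distinct labels")
  }
  sets <- lapply(presence, function(x) unique(as.character(x)))
  universe <- sort(unique(unlist(sets)))
  membership <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L)
  regions <- list()
  # every nonempty subset of groups = one exclusive region
  for (size in seq_len(k)) {
    combos <- utils::combn(labs, size, simplify = FALSE)
    for (cmb in combos) {
      inside <- rowSums(membership[, cmb, drop = FALSE]) == length(cmb)
      exact <- inside & rowSums(membership) == length(cmb)
      regions[[paste(cmb, collapse = "&")]] <- universe[exact]
    }
  }
  structure(
    list(regions = regions,
         counts = vapply(regions, length, integer(1)),
         universe = universe),
    class = "detection_sets"
  )
}

#' Retain proteins by ortholog sequence similarity
#'
#' Keeps proteins whose percent amino acid similarity to their human
#' ortholog is strictly greater than 99 (the study's retention rule for
#' mapping canine identifications onto human annotation).
#'
#' @param rows data.frame with columns `protein_id` and
#'   `percent_similarity` (values in \[0, 100\]).
#' @param min_similarity exclusive threshold, default 99.
#' @return character vector of retained protein ids, sorted.
#' @examples
#' ortholog_similarity_filter(data.frame(
#'   protein_id = c("P1", "P2", "P3"),
#'   percent_similarity = c(99.5, 98, 100)))
#' @export
ortholog_similarity_filter <- function(rows, min_similarity = 99) {
  if (nrow(rows) == 0L) return(character(0))
  s <- rows$percent_similarity
  if (any(is.na(s)) || any(s < 0 | s > 100)) {
    stop_data("percent_similarity must lie in [0, 100]")
  }
  sort(as.character(rows$protein_id[s > min_similarity]))
}

#' Gene-set enrichment by odds ratio and hypergeometric tail
#'
#' For each gene set, tabulates the 2x2 contingency of query membership vs
#' set membership over the background and reports the sample odds ratio
#' (with a Haldane-Anscombe 0.5 correction when any cell is zero) plus the
#' one-sided enrichment p-value from the hypergeometric upper tail -- the
#' statistic displayed in the study's pathway bar charts.
#'
#' @param query character vector of ids, a subset of the background.
#' @param collection list of class `gene_set_collection` from [read_gmt()]
#'   or a plain list with elements `sets` (named list of id vectors) and
#'   `background` (character universe).
#' @return data.frame with `set`, `overlap`, `set_size`, `query_size`,
#'   `odds_ratio`, `p_value`, sorted by ascending p then set name.
#' @examples
#' coll <- list(sets = list(S = as.character(1:5)),
#'              background = as.character(1:20))
#' enrichment_odds_ratios(as.character(c(1, 2, 3, 10, 11, 12)), coll)
#' @export
enrichment_odds_ratios <- function(query, collection) {
  bg <- unique(as.character(collection$background))
  query <- unique(as.character(query))
  if (length(query) == 0L || length(bg) == 0L) {
    stop_config("query and background must be nonempty")
  }
  if (!all(query %in% bg)) stop_data("query contains ids outside the background")
  rows <- lapply(names(collection$sets), function(nm) {
    set <- unique(as.character(collection$sets[[nm]]))
    set <- set[set %in% bg]
    a <- sum(query %in% set)               # in query, in set
    b <- length(query) - a                 # in query, not in set
    cc <- length(set) - a                  # not in query, in set
    d <- length(bg) - a - b - cc
    if (min(a, b, cc, d) == 0) {
      or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
    } else {
      or <- (a * d) / (b * cc)
    }
    p <- stats::phyper(a - 1, length(set), length(bg) - length(set),
                       length(query), lower.tail = FALSE)
    data.frame(set = nm, overlap = a, set_size = length(set),
               query_size = length(query), odds_ratio = or, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, out$set), ]
  rownames(out) <- NULL
  out
}

#' Read a GMT gene-set file
#'
#' Standard tab-separated format: set name, description, then member ids.
#'
#' @param path GMT file path.
#' @param background optional id universe; defaults to the union of all
#'   set members.
#' @return list of class `gene_set_collection` with `sets`, `descriptions`
#'   and `background`.
#' @export
read_gmt <- function(path, background = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 3L
  if (any(bad)) stop_data("GMT line(s) with fewer than 3 fields: ",
                          paste(which(bad), collapse = ", "))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(names(sets))) stop_data("duplicate set names in GMT")
  if (is.null(background)) background <- sort(unique(unlist(sets)))
  structure(
    list(sets = sets,
         descriptions = stats::setNames(
           vapply(parts, `[[`, character(1), 2L), names(sets)),
         background = unique(as.character(background))),
    class = "gene_set_collection"
  )
}
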