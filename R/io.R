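delim_for <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

#' Read a peptide or protein abundance matrix
#'
#' TSV is the canonical on-disk format (CSV accepted by extension). Peptide
#' tables start with `peptide_id` and `protein_id` columns; protein tables
#' with `protein_id`. Blank cells become missing values (`NA`), never zero:
#' the quantifier pairs only observed replicates, and the two conventions
#' give different fold changes.
#'
#' @param path file path.
#' @param kind `"peptide"` or `"protein"`.
#' @return peptide tables: data.frame (`peptide_id`, `protein_id`, sample
#'   columns); protein tables: numeric matrix with protein row names.
#' @export
read_matrix <- function(path, kind = c("peptide", "protein")) {
  kind <- match.arg(kind)
  df <- utils::read.table(path, sep = delim_for(path), header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  id_cols <- if (kind == "peptide") c("peptide_id", "protein_id") else "protein_id"
  if (!identical(names(df)[seq_along(id_cols)], id_cols)) {
    stop_data(path, ": header must start with ",
              paste(id_cols, collapse = ", "))
  }
  key <- df[[1]]
  dup <- key[duplicated(key)]
  if (length(dup)) {
    stop_data(path, ": duplicate ", id_cols[1], ": ",
              paste(unique(dup), collapse = ", "))
  }
  vals <- df[, setdiff(names(df), id_cols), drop = FALSE]
  for (j in names(vals)) {
    x <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(!is.na(x) & x < 0)
    if (length(bad)) {
      stop_data(path, ": negative abundance in column ", j, ", row(s) ",
                paste(bad, collapse = ", "))
    }
    vals[[j]] <- x
  }
  if (kind == "peptide") {
    cbind(df[id_cols], vals)
  } else {
    m <- as.matrix(vals)
    rownames(m) <- key
    m
  }
}

#' Write a peptide table as TSV
#' @param tbl peptide data.frame from [simulate_peptide_table()].
#' @param path output path.
#' @export
write_peptide_table <- function(tbl, path) {
  utils::write.table(tbl, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Write a protein matrix as TSV (first column `protein_id`)
#' @param mat numeric protein x sample matrix.
#' @param path output path.
#' @export
write_protein_table <- function(mat, path) {
  df <- data.frame(protein_id = rownames(mat), mat,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write a sample sheet (CSV)
#'
#' Columns: `sample_id` (unique), `group`, `cohort`, `replicate`,
#' `dfi_days`; missing fields stay `NA`.
#' @param path CSV path.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  if (!"sample_id" %in% names(df)) stop_data(path, ": sample_id column required")
  if (anyDuplicated(df$sample_id)) stop_data(path, ": duplicate sample_id")
  df
}

#' @rdname read_sample_sheet
#' @param sheet sample-sheet data.frame.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.csv(sheet, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write simulation ground truth as JSON
#' @param truth truth record from a generator.
#' @param path output path.
#' @export
write_sim_truth <- function(truth, path) {
  truth$generating_params <- unclass(truth$generating_params)
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

pipeline_keys <- list(
  top = c("out_dir", "seed", "stages", "quantify", "signature", "prognose"),
  quantify = c("peptides", "samples", "group_a", "group_b", "min_fold"),
  signature = c("proteins", "samples", "cohort1", "cohort2",
                "reference_cohort", "gmt", "eps"),
  prognose = c("proteins", "samples", "good", "poor", "p_cutoff",
               "max_features", "loo")
)

check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown)) {
    stop_config("unknown config key(s) in ", where, ": ",
                paste(unknown, collapse = ", "))
  }
}

#' Run the pipeline end to end from a config
#'
#' Executes any subset of quantify (fold changes + threshold filter),
#' signature (normalization, t-scores, heatmap matrix, optional
#' enrichment) and prognose (signature training + leave-one-out scores),
#' writing each stage's tables under `out_dir` together with a provenance
#' manifest (package version, seed, resolved config, input file hashes).
#' Identical config and inputs give identical outputs. Unknown config keys
#' are rejected before any computation.
#'
#' @param cfg config list, or path to a YAML file with the same structure:
#'   top-level `out_dir`, `seed`, `stages` (subset of `"quantify"`,
#'   `"signature"`, `"prognose"`) and one block per stage (see
#'   `exosig:::pipeline_keys` for the accepted fields).
#' @return the output directory, invisibly.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg) && length(cfg) == 1L) cfg <- yaml::read_yaml(cfg)
  check_keys(cfg, pipeline_keys$top, "top level")
  if (is.null(cfg$out_dir)) stop_config("config needs out_dir")
  stages <- cfg$stages %||% intersect(c("quantify", "signature", "prognose"),
                                      names(cfg))
  bad <- setdiff(stages, c("quantify", "signature", "prognose"))
  if (length(bad)) stop_config("unknown stage(s): ", paste(bad, collapse = ", "))
  for (s in stages) check_keys(cfg[[s]], pipeline_keys[[s]], s)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- character(0)
  run_stage <- function(stage, fn) {
    message("[exosig] running stage: ", stage)
    tryCatch(fn(), error = function(e) {
      stop_data("stage '", stage, "' failed: ", conditionMessage(e))
    })
  }

  if ("quantify" %in% stages) {
    q <- cfg$quantify
    inputs <- c(inputs, q$peptides, q$samples)
    run_stage("quantify", function() {
      tbl <- read_matrix(q$peptides, "peptide")
      sheet <- read_sample_sheet(q$samples)
      fc <- fold_change_table(tbl, sheet, q$group_a, q$group_b)
      utils::write.table(fc, file.path(cfg$out_dir, "fold_changes.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (!is.null(q$min_fold)) {
        hits <- threshold_filter(fc, q$min_fold, "over")
        writeLines(hits, file.path(cfg$out_dir, "fold_change_hits.txt"))
      }
    })
  }

  if ("signature" %in% stages) {
    s <- cfg$signature
    inputs <- c(inputs, s$proteins, s$samples, s$gmt)
    run_stage("signature", function() {
      mat <- read_matrix(s$proteins, "protein")
      sheet <- read_sample_sheet(s$samples)
      scores <- feature_t_scores(mat, sheet, s$cohort1, s$cohort2)
      utils::write.table(scores, file.path(cfg$out_dir, "t_scores.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      ref <- s$reference_cohort %||% s$cohort1
      hm <- heatmap_matrix(mat, sheet, ref, scores,
                           eps = s$eps %||% NULL)
      utils::write.table(
        data.frame(protein_id = rownames(hm$values), hm$values,
                   check.names = FALSE),
        file.path(cfg$out_dir, "heatmap_log2_vs_reference.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      if (!is.null(s$gmt)) {
        coll <- read_gmt(s$gmt, background = rownames(mat))
        top <- scores$protein_id[scores$p_value < 0.05]
        if (length(top)) {
          enr <- enrichment_odds_ratios(top, coll)
          utils::write.table(enr, file.path(cfg$out_dir, "enrichment.tsv"),
                             sep = "\t", quote = FALSE, row.names = FALSE)
        }
      }
    })
  }

  if ("prognose" %in% stages) {
    p <- cfg$prognose
    inputs <- c(inputs, p$proteins, p$samples)
    run_stage("prognose", function() {
      mat <- read_matrix(p$proteins, "protein")
      sheet <- read_sample_sheet(p$samples)
      model <- train_signature(mat, sheet, p$good, p$poor,
                               max_features = p$max_features %||% Inf,
                               p_cutoff = p$p_cutoff %||% 0.05)
      jsonlite::write_json(
        list(selected_features = model$selected_features,
             weight = as.list(model$weight),
             standardization = lapply(model$standardization, as.list),
             boundary = model$boundary, orientation = model$orientation),
        file.path(cfg$out_dir, "signature_model.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
      if (isTRUE(p$loo)) {
        loo <- loo_accuracy(mat, sheet, p$good, p$poor,
                            max_features = p$max_features %||% Inf,
                            p_cutoff = p$p_cutoff %||% 0.05)
        utils::write.table(loo$decompositions,
                           file.path(cfg$out_dir, "prognosis_scores.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        writeLines(format(loo$accuracy),
                   file.path(cfg$out_dir, "loo_accuracy.txt"))
      }
    })
  }

  inputs <- unique(inputs[!vapply(inputs, is.null, logical(1))])
  manifest <- list(
    package = "exosig",
    version = as.character(utils::packageVersion("exosig")),
    seed = cfg$seed,
    stages = stages,
    config = cfg,
    input_md5 = as.list(tools::md5sum(inputs))
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(cfg$out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
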