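#' Read a participant-indexed analysis table
#'
#' Reads a TSV/CSV table with a header, enforces a schema of required
#' columns, checks participant identifiers for duplicates and returns the
#' numeric matrix plus labels.  Alignment between blocks is always by the
#' identifier column, never by row order.
#'
#' @param path file path (tab- or comma-separated, inferred from the
#'   extension; `.tsv` default).
#' @param required character vector of column names that must be present
#'   (besides the id column).
#' @param id_col name of the identifier column (default
#'   `"participant_id"`); use `NULL` for tables without ids.
#' @return list with `data` (numeric matrix, rownames = ids), `ids`, and
#'   `missing_report` (count of NAs per column).
#' @export
read_cohort_table <- function(path, required = NULL, id_col = "participant_id") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(required)) {
    miss <- setdiff(required, names(df))
    if (length(miss)) {
      stop(sprintf("missing required column(s): %s", paste(miss, collapse = ", ")),
           call. = FALSE)
    }
  }
  ids <- NULL
  if (!is.null(id_col) && id_col %in% names(df)) {
    ids <- as.character(df[[id_col]])
    if (anyDuplicated(ids)) {
      stop(sprintf("duplicate participant ids in %s", path), call. = FALSE)
    }
    df[[id_col]] <- NULL
  }
  non_num <- names(df)[!vapply(df, is.numeric, TRUE)]
  if (length(non_num)) {
    stop(sprintf("non-numeric column(s) in %s: %s (mixed decimal separators?)",
                 path, paste(non_num, collapse = ", ")), call. = FALSE)
  }
  m <- as.matrix(df)
  rownames(m) <- ids
  list(data = m, ids = ids,
       missing_report = colSums(is.na(m)))
}

#' Write a synthetic cohort to a directory of TSV files
#'
#' Emits `confounders.tsv`, `pa.tsv`, `fc.tsv`, `gmv.tsv`, `disease.tsv`
#' (each with a `participant_id` column), `edge_labels.tsv` (the netmat
#' vectorization convention) and `ground_truth.json`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- cohort$config$n_participants
  ids <- sprintf("P%06d", seq_len(n))
  wr <- function(m, name) {
    df <- data.frame(participant_id = ids, m, check.names = FALSE)
    write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  wr(cohort$confounders, "confounders.tsv")
  wr(cohort$pa, "pa.tsv")
  wr(cohort$fc_edges, "fc.tsv")
  wr(cohort$gmv, "gmv.tsv")
  wr(cohort$disease, "disease.tsv")
  write.table(netmat_edge_labels(cohort$config$n_fc_nodes),
              file.path(dir, "edge_labels.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  gt <- cohort$ground_truth
  gt$seed <- cohort$config$seed
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' Blocks are re-aligned by participant id (an error if the id sets
#' differ), so the row order on disk is immaterial.
#'
#' @param dir cohort directory.
#' @return list with `confounders` (data.frame), `pa`, `fc_edges`, `gmv`,
#'   `disease` matrices and `ground_truth` (if present), of class
#'   `synthetic_cohort` minus config.
#' @export
read_cohort <- function(dir) {
  rd <- function(name) read_cohort_table(file.path(dir, name))
  blocks <- list(confounders = rd("confounders.tsv"),
                 pa = rd("pa.tsv"), fc_edges = rd("fc.tsv"),
                 gmv = rd("gmv.tsv"), disease = rd("disease.tsv"))
  ids <- blocks$confounders$ids
  for (b in names(blocks)) {
    if (!setequal(blocks[[b]]$ids, ids)) {
      stop(sprintf("participant ids in %s do not match confounders.tsv", b),
           call. = FALSE)
    }
    blocks[[b]] <- blocks[[b]]$data[ids, , drop = FALSE]
  }
  gt_path <- file.path(dir, "ground_truth.json")
  gt <- if (file.exists(gt_path)) jsonlite::read_json(gt_path, simplifyVector = TRUE)
  out <- list(confounders = as.data.frame(blocks$confounders),
              pa = blocks$pa, fc_edges = blocks$fc_edges,
              gmv = blocks$gmv, disease = blocks$disease,
              ground_truth = gt)
  out
}

#' Run the full three-stage pipeline on a cohort
#'
#' Orchestrates the analysis end to end: bipartial CCA of PA against the
#' chosen imaging block, mass-univariate screening with BH control plus
#' cross-validated predictive correlations and the three importance
#' engines, and the nested logistic disease panel.  Writes result tables
#' and a JSON run manifest (settings, seeds, per-stage wall-clock and
#' output checksums) under `out_dir`; each stage's outputs are plain TSV
#' so stages are independently re-runnable and auditable.
#'
#' @param cohort cohort list (from [generate_cohort()] or
#'   [read_cohort()]).
#' @param out_dir output directory.
#' @param idp imaging block to analyse: `"fc"` or `"gmv"`.
#' @param stages subset of `c("cca", "importance", "risk")`.
#' @param n_perm CCA permutations.
#' @param alpha BH level for the screen.
#' @param cv_reps repetitions for predictive correlation and risk CV.
#' @param n_trees random-forest size.
#' @param seed master seed; per-stage seeds derive from it.
#' @return the run manifest (list), invisibly; written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(cohort, out_dir, idp = c("fc", "gmv"),
                         stages = c("cca", "importance", "risk"),
                         n_perm = 199L, alpha = 0.05, cv_reps = 10L,
                         n_trees = 200L, seed = 1L) {
  idp <- match.arg(idp)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  Y <- if (idp == "fc") cohort$fc_edges else cohort$gmv
  G <- as_numeric_matrix(cohort$confounders)
  manifest <- list(version = as.character(utils::packageVersion("pabrain")),
                   idp = idp, stages = stages, seed = seed,
                   n = nrow(Y), q = ncol(Y),
                   settings = list(n_perm = n_perm, alpha = alpha,
                                   cv_reps = cv_reps, n_trees = n_trees),
                   stage = list())
  tsv <- function(df, name) {
    p <- file.path(out_dir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  stamp <- function(name, t0, files) {
    manifest$stage[[name]] <<- list(
      seconds = round(as.numeric(Sys.time()) - t0, 2),
      outputs = lapply(setNames(files, basename(files)),
                       function(f) unname(tools::md5sum(f))))
  }

  if ("cca" %in% stages) {
    t0 <- as.numeric(Sys.time())
    fit <- bipartial_cca(cohort$pa, Y, confounders_x = G, confounders_y = G,
                         n_perm = n_perm, seed = seed)
    f1 <- tsv(summary(fit)$table, sprintf("cca_%s_modes.tsv", idp))
    f2 <- tsv(data.frame(variable = names(fit$cross_loadings_x),
                         loading = fit$cross_loadings_x),
              sprintf("cca_%s_loadings.tsv", idp))
    if (length(fit$rho) > 1L) {
      message("note: permutation inference past the primary CCA mode may ",
              "violate exchangeability after residualization; modes > 1 are caveated")
    }
    stamp("cca", t0, c(f1, f2))
  }

  if ("importance" %in% stages) {
    t0 <- as.numeric(Sys.time())
    scr <- screen_responses(Y, G, cohort$pa, alpha = alpha)
    X_pred <- cbind(G, cohort$pa)
    cvc <- vapply(scr$selected, function(l)
      cv_predictive_correlation(Y[, l], X_pred, n_reps = cv_reps,
                                seed = seed + l)$mean, 0)
    it <- importance_ttest(Y[, scr$selected, drop = FALSE], G, cohort$pa)
    ib <- importance_stepwise_bic(Y[, scr$selected, drop = FALSE], G, cohort$pa)
    irf <- importance_random_forest(Y, G, cohort$pa, n_trees = n_trees,
                                    seed = seed)
    cons <- consensus_ranking(list(it, ib, irf))
    f1 <- tsv(data.frame(response = colnames(Y),
                         p_value = scr$p_value, p_adjusted = scr$p_adjusted,
                         selected = seq_len(ncol(Y)) %in% scr$selected),
              sprintf("screen_%s.tsv", idp))
    f2 <- tsv(data.frame(response = colnames(Y)[scr$selected],
                         cv_correlation = cvc),
              sprintf("cvcorr_%s.tsv", idp))
    f3 <- tsv(cons, sprintf("importance_consensus_%s.tsv", idp))
    stamp("importance", t0, c(f1, f2, f3))
  }

  if ("risk" %in% stages) {
    t0 <- as.numeric(Sys.time())
    panel <- run_disease_panel(cohort, idp = idp, n_reps = cv_reps,
                               seed = seed)
    f1 <- tsv(panel$table, sprintf("risk_panel_%s.tsv", idp))
    jsonlite::write_json(panel$table, file.path(out_dir, sprintf("risk_panel_%s.json", idp)),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    stamp("risk", t0, f1)
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
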