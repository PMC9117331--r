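## Shared readers/writers and the umbrella pipeline driver. All artifacts
## are plain comma-separated text (UTF-8, header row, '.' decimal,
## missing values as empty fields) so a run can be resumed or audited
## without opaque binary state.

cell_table_schema <- c("well", "drug", "time", "clone", "pathway", "mode",
                       "readout_ratio", "readout_nuclear")

#' Read / write a per-cell screen table
#'
#' CSV with columns `well`, `drug`, `time`, `clone`, `pathway`, `mode`,
#' `readout_ratio`, `readout_nuclear` (and optionally `cell_area`).
#' Schema violations are reported with the offending columns.
#'
#' @param path File path.
#' @return data.frame of cells.
#' @export
read_cell_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(cell_table_schema, names(df))
  if (length(missing))
    stop("cell table ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  for (col in c("time", "readout_ratio", "readout_nuclear"))
    if (!is.numeric(df[[col]])) df[[col]] <- as.numeric(df[[col]])
  df
}

#' @rdname read_cell_table
#' @param cells Cell data.frame.
#' @export
write_cell_table <- function(cells, path) {
  missing <- setdiff(cell_table_schema, names(cells))
  if (length(missing))
    stop("cell table lacks column(s): ", paste(missing, collapse = ", "))
  utils::write.csv(cells, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a plate map
#'
#' CSV mapping wells to treatments: columns `well`, `drug` (and any
#' extra metadata). Validation fails fast when no control (`DMSO`)
#' wells are present.
#'
#' @param path File path.
#' @param control Control label that must appear (default `"DMSO"`).
#' @return data.frame.
#' @export
read_platemap <- function(path, control = "DMSO") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("well", "drug"), names(df))
  if (length(missing))
    stop("plate map lacks column(s): ", paste(missing, collapse = ", "))
  if (!any(df$drug == control))
    stop("plate map has no '", control, "' control wells")
  df
}

#' Read / write a long-format score matrix
#'
#' Columns `drug`, `pathway`, `time`, `score`, `n_treated`,
#' `n_control`, `valid`; invalid scores are empty fields. The
#' write/read round trip preserves the table exactly.
#'
#' @param scores A `score_matrix`.
#' @param path File path.
#' @export
write_score_matrix <- function(scores, path) {
  utils::write.csv(scores, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_score_matrix
#' @export
read_score_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(drug = "character",
                                       pathway = "character"))
  df$valid <- as.logical(df$valid)
  class(df) <- c("score_matrix", "data.frame")
  df
}

#' Run the full screen-analysis pipeline on simulated inputs
#'
#' Drives simulate -> score -> threshold -> state analysis -> growth ->
#' cohort similarity with stage toggles, writing every stage artifact
#' as CSV plus a JSON manifest (seed, stage toggles, session versions)
#' into `out_dir`. Two runs with the same design and seed produce
#' identical artifacts.
#'
#' @param design A [screen_design()]; its `seed` governs all
#'   randomness.
#' @param out_dir Output directory (created).
#' @param stages Character subset of
#'   `c("score", "states", "growth", "similarity")`.
#' @param k Cluster count for the state analysis.
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(design, out_dir,
                         stages = c("score", "states", "growth",
                                    "similarity"),
                         k = 3) {
  stopifnot(inherits(design, "screen_design"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  sim <- simulate_screen(design)
  write_cell_table(sim$cells, file.path(out_dir, "cells.csv"))
  res$truth <- sim$truth
  if ("score" %in% stages) {
    scores <- score_screen(sim$cells)
    write_score_matrix(scores, file.path(out_dir, "scores.csv"))
    thr <- derive_threshold(dmso_null_scores(sim$cells))
    res$scores <- scores
    res$threshold <- thr
    res$active <- active_drugs(scores, thr)
    writeLines(res$active, file.path(out_dir, "active_drugs.txt"))
  }
  if ("states" %in% stages && !is.null(res$scores)) {
    m <- score_slice(res$scores, max(design$timepoints),
                     drop_incomplete = TRUE)
    m <- m[rowSums(is.na(m)) == 0, , drop = FALSE]
    pca <- fit_pca(m, orient = sim$truth$u[match(colnames(m),
                                                 design$pathways$pathway)])
    cl <- cluster_drugs(m, k = k)
    metrics <- drug_state_metrics(pca)
    metrics$cluster <- cl$labels[metrics$drug]
    utils::write.csv(metrics, file.path(out_dir, "state_metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(pca$loadings, file.path(out_dir, "pca_loadings.csv"))
    res$pca <- pca
    res$clusters <- cl
    res$metrics <- metrics
  }
  if ("growth" %in% stages) {
    seeds <- child_seeds(design$seed, c("growth_ctrl", "growth_drugs"))
    truth <- sim$truth
    ctrl_tc <- simulate_growth_timecourse(truth$gamma0,
                                          log(2) / truth$alpha0,
                                          times = design$timepoints,
                                          noise_cv = 0.05,
                                          seed = seeds["growth_ctrl"])
    ctrl_fit <- fit_growth_model(ctrl_tc)
    gseeds <- child_seeds(seeds["growth_drugs"], truth$drugs$drug)
    growth <- do.call(rbind, lapply(seq_len(nrow(truth$drugs)), function(i) {
      tc <- simulate_growth_timecourse(truth$drugs$gamma[i],
                                       log(2) / truth$drugs$alpha[i],
                                       times = design$timepoints,
                                       noise_cv = 0.05, seed = gseeds[i])
      est <- fit_growth_model(tc)
      nc <- normalize_to_control(est, ctrl_fit)
      data.frame(drug = truth$drugs$drug[i], gamma = est$gamma,
                 alpha = est$alpha, tau = est$tau,
                 gamma_norm = nc$gamma_norm, alpha_norm = nc$alpha_norm,
                 imbalance = nc$imbalance, limitation = nc$limitation,
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(growth, file.path(out_dir, "growth.csv"),
                     row.names = FALSE)
    res$growth <- growth
    if (!is.null(res$metrics)) {
      sizes <- per_drug_cell_size(sim$cells)
      pc1 <- setNames(res$metrics$pc1, res$metrics$drug)
      res$size_state <- size_state_correlation(sizes, pc1)
    }
  }
  if ("similarity" %in% stages && !is.null(res$scores)) {
    ref <- pathway_correlations(score_slice(res$scores,
                                            max(design$timepoints),
                                            drop_incomplete = TRUE))
    seeds <- child_seeds(design$seed, "cohorts")
    cohorts <- simulate_cohort_proteomes(nearest_correlation(ref),
                                         n_samples = 500, n_cohorts = 3,
                                         seed = seeds[1])
    sim_scores <- lapply(cohorts, function(co) {
      cc <- cohort_correlations(co)
      if (is.null(cc)) return(NULL)
      similarity_to_reference(cc, ref)
    })
    overall <- vapply(sim_scores,
                      function(s) if (is.null(s)) NA_real_
                                  else attr(s, "overall"), 0)
    utils::write.csv(data.frame(cohort = seq_along(overall),
                                similarity = overall),
                     file.path(out_dir, "cohort_similarity.csv"),
                     row.names = FALSE)
    res$cohort_similarity <- overall
  }
  manifest <- list(package = "pathscreen",
                   version = as.character(utils::packageVersion("pathscreen")),
                   r_version = R.version.string,
                   seed = design$seed, stages = stages,
                   timepoints = design$timepoints,
                   n_drugs = design$n_pos + design$n_neg + design$n_idio)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}

# Project a symmetric matrix with unit diagonal to the nearest (in the
# eigenvalue-clipping sense) positive-semidefinite correlation matrix.
nearest_correlation <- function(r) {
  r <- (r + t(r)) / 2
  e <- eigen(r, symmetric = TRUE)
  v <- pmax(e$values, 1e-8)
  out <- e$vectors %*% diag(v) %*% t(e$vectors)
  d <- sqrt(diag(out))
  out <- out / (d %o% d)
  dimnames(out) <- dimnames(r)
  out
}
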