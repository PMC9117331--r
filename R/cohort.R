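#' Pairwise protein correlations of a cohort
#'
#' Full pairwise Pearson correlation matrix of a sample-by-protein
#' cohort, computed only for cohorts with strictly more than `min_n`
#' samples ("over 30 samples"); smaller cohorts are skipped with a
#' logged reason. Constant protein columns yield `NA` rows with a
#' warning.
#'
#' @param cohort Numeric sample x protein matrix (columns named).
#' @param min_n Minimum sample count; cohorts with `n <= min_n` are
#'   skipped (default 30).
#' @return Protein x protein correlation matrix, or `NULL` (with a
#'   message and attribute-free return) when skipped.
#' @export
cohort_correlations <- function(cohort, min_n = 30) {
  cohort <- as.matrix(cohort)
  n <- nrow(cohort)
  if (n <= min_n) {
    message("cohort skipped: ", n, " samples (need more than ", min_n, ")")
    return(NULL)
  }
  sds <- apply(cohort, 2, sd)
  if (any(sds == 0))
    warning("constant protein column(s): ",
            paste(colnames(cohort)[sds == 0], collapse = ", "))
  r <- suppressWarnings(cor(cohort, use = "pairwise.complete.obs"))
  diag(r) <- 1
  r
}

#' Row-wise similarity of a cohort correlation matrix to a reference
#'
#' The diagonal (trivially 1) is removed from both matrices; then for
#' every protein the cohort's off-diagonal correlation row is Pearson-
#' correlated with the corresponding reference row, aligned by protein
#' identity (pairwise-complete, requiring at least 4 shared finite
#' entries). The overall score is the mean over proteins.
#'
#' @param cohort_corr,reference_corr Protein x protein correlation
#'   matrices over matching (named) panels; order may differ.
#' @return Object of class `similarity_score`: data.frame with one row
#'   per protein (`protein`, `similarity`) plus attribute `overall`.
#' @export
similarity_to_reference <- function(cohort_corr, reference_corr) {
  cohort_corr <- as.matrix(cohort_corr)
  reference_corr <- as.matrix(reference_corr)
  cn <- colnames(cohort_corr); rn <- colnames(reference_corr)
  if (is.null(cn) || is.null(rn))
    stop("both matrices need protein column names")
  unmatched <- c(setdiff(cn, rn), setdiff(rn, cn))
  if (length(unmatched))
    stop("protein panels differ: ", paste(unique(unmatched), collapse = ", "))
  cohort_corr <- cohort_corr[rn, rn]
  p <- length(rn)
  sim <- vapply(seq_len(p), function(i) {
    a <- cohort_corr[i, -i]; b <- reference_corr[i, -i]
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 4) return(NA_real_)
    suppressWarnings(cor(a[ok], b[ok]))
  }, 0)
  out <- data.frame(protein = rn, similarity = sim,
                    stringsAsFactors = FALSE)
  attr(out, "overall") <- mean(sim, na.rm = TRUE)
  class(out) <- c("similarity_score", "data.frame")
  out
}

#' @export
print.similarity_score <- function(x, ...) {
  cat("Correlation-structure similarity (overall",
      sprintf("%.3f", attr(x, "overall")), ")\n")
  print.data.frame(x)
  invisible(x)
}

#' Enrichment strength
#'
#' The log-ratio `log10(observed / expected)` used to express how large
#' an enrichment effect is. `observed = 0` is reported as `NA` with a
#' warning (the log-ratio is `-Inf`).
#'
#' @param observed Observed count(s), >= 0.
#' @param expected Expected count(s), > 0.
#' @return Numeric vector of strengths.
#' @export
enrichment_strength <- function(observed, expected) {
  if (any(expected <= 0)) stop("'expected' must be positive")
  if (any(observed < 0)) stop("'observed' must be nonnegative")
  out <- suppressWarnings(log10(observed / expected))
  if (any(observed == 0)) {
    warning("observed = 0: enrichment strength reported as NA")
    out[observed == 0] <- NA_real_
  }
  out
}
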