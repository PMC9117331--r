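#' Hierarchical clustering of drug response signatures
#'
#' Agglomerative clustering of drugs by their pathway activity-score
#' signatures, using Euclidean distance and Ward linkage in the
#' squared-distance ("ward.D2") convention, cut at `k` clusters.
#' Pathways carrying any missing value are dropped first (mirroring the
#' practice of discarding a reporter that was not measured throughout).
#'
#' @param m Numeric drug x pathway matrix (e.g. from [score_slice()]).
#' @param k Number of clusters (default 3).
#' @return Object of class `drug_clusters`: list with `labels` (named
#'   cluster letters, ordered by cluster size), `tree` (the `hclust`
#'   object), `k`, and `pathways_used`.
#' @export
cluster_drugs <- function(m, k = 3) {
  m <- as.matrix(m)
  keep <- colSums(is.na(m)) == 0
  if (!all(keep))
    message("dropping pathway(s) with missing scores: ",
            paste(colnames(m)[!keep], collapse = ", "))
  m <- m[, keep, drop = FALSE]
  if (k > nrow(m)) stop("k exceeds the number of drugs")
  tree <- hclust(dist(m, method = "euclidean"), method = "ward.D2")
  cl <- cutree(tree, k = k)
  # stable letter labels: largest cluster first
  sizes <- sort(table(cl), decreasing = TRUE)
  relab <- setNames(LETTERS[seq_len(k)], names(sizes))
  labels <- setNames(relab[as.character(cl)], rownames(m))
  structure(list(labels = labels, tree = tree, k = k,
                 pathways_used = colnames(m)),
            class = "drug_clusters")
}

#' @export
print.drug_clusters <- function(x, ...) {
  cat("Drug clustering (Euclidean / Ward.D2), k =", x$k, "\n")
  print(table(x$labels))
  invisible(x)
}

#' Pathway-pathway Pearson correlation matrix
#'
#' Pairwise Pearson correlations between pathway activity signatures
#' across drugs, with pairwise-complete handling of missing scores.
#' Zero-variance pathways yield `NA` rows/columns with a warning.
#'
#' @param m Numeric drug x pathway matrix (>= 3 drugs).
#' @return Symmetric pathway x pathway correlation matrix with unit
#'   diagonal.
#' @export
pathway_correlations <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 3) stop("need at least 3 drugs")
  sds <- apply(m, 2, sd, na.rm = TRUE)
  if (any(!is.na(sds) & sds == 0))
    warning("zero-variance pathway(s): ",
            paste(colnames(m)[!is.na(sds) & sds == 0], collapse = ", "))
  r <- suppressWarnings(cor(m, use = "pairwise.complete.obs"))
  diag(r) <- 1
  r
}

#' PCA coordinate system of drug response signatures
#'
#' Column-centered, unscaled principal component analysis (scores are
#' already on a common `[-1, 1]` activity scale) via singular value
#' decomposition. The sign of every component is fixed deterministically
#' (its largest-|loading| entry is made positive); optionally the first
#' component is oriented to have a positive inner product with a given
#' pathway-space direction, which fixes which signaling state maps to
#' positive PC1.
#'
#' @param m Numeric drug x pathway matrix without missing values
#'   (>= 2 drugs, >= 2 pathways).
#' @param orient Optional numeric vector over pathways; if given, PC1 is
#'   flipped (loadings and coordinates) so its loading vector has
#'   positive dot product with `orient`.
#' @return Object of class `state_pca`: `loadings` (orthonormal columns),
#'   `sdev`, `variance` (per-axis variances), `explained` (fractions
#'   summing to 1), `center`, and `coordinates` (drug x component
#'   scores).
#' @export
fit_pca <- function(m, orient = NULL) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("missing values: drop incomplete pathways first")
  if (nrow(m) < 2 || ncol(m) < 2) stop("need >= 2 drugs and >= 2 pathways")
  if (all(apply(m, 2, sd) == 0)) stop("rank-0 input: no variance")
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  rot <- pc$rotation; sco <- pc$x
  for (j in seq_len(ncol(rot))) {
    i_max <- which.max(abs(rot[, j]))
    if (rot[i_max, j] < 0) { rot[, j] <- -rot[, j]; sco[, j] <- -sco[, j] }
  }
  if (!is.null(orient)) {
    if (length(orient) != nrow(rot))
      stop("'orient' length must match the pathway count")
    if (sum(rot[, 1] * orient) < 0) {
      rot[, 1] <- -rot[, 1]; sco[, 1] <- -sco[, 1]
    }
  }
  v <- pc$sdev^2
  structure(list(loadings = rot, sdev = pc$sdev, variance = v,
                 explained = v / sum(v), center = pc$center,
                 coordinates = sco),
            class = "state_pca")
}

#' @export
print.state_pca <- function(x, ...) {
  cat("State PCA:", nrow(x$loadings), "pathways,",
      nrow(x$coordinates), "drugs\n")
  cat("PC1 explains", sprintf("%.1f%%", 100 * x$explained[1]),
      "of variance\n")
  invisible(x)
}

#' Project drug signatures onto a fitted PCA coordinate system
#'
#' @param object A `state_pca`.
#' @param newdata Drug x pathway matrix on the same pathways.
#' @param ... Unused.
#' @return Drug x component coordinate matrix.
#' @export
predict.state_pca <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  sweep(newdata, 2, object$center) %*% object$loadings
}

#' Variance-product persistence metric (phi)
#'
#' Quantifies how well a reference orthonormal coordinate system (a PCA
#' basis fitted to pre-treatment measurements) captures the correlation
#' structure of new data: the product of per-axis variances of the data
#' projected onto the reference basis, divided by the product of per-axis
#' variances on the original pathway axes. Computed in log space.
#' Values near 1 mean the reference axes describe the data no better
#' than the raw axes (uncorrelated data); values near 0 mean the data
#' concentrate along reference directions (strong correlations captured
#' by the reference). For any orthonormal basis phi is in (0, 1] when
#' variances are positive, and the minimum over bases is attained at the
#' data's own eigenbasis, where phi equals det(covariance) divided by
#' the product of the per-pathway variances.
#'
#' @param data Drug x pathway matrix (no missing values).
#' @param reference A `state_pca` or an orthonormal loading matrix with
#'   as many rows as `data` has pathways.
#' @return phi (single positive number).
#' @export
phi_metric <- function(data, reference) {
  data <- as.matrix(data)
  if (anyNA(data)) stop("missing values in 'data'")
  basis <- if (inherits(reference, "state_pca")) reference$loadings
           else as.matrix(reference)
  p <- ncol(data)
  if (nrow(basis) != p || ncol(basis) != p)
    stop("reference dimension must match the pathway count")
  if (max(abs(crossprod(basis) - diag(p))) > 1e-8)
    stop("reference basis is not orthonormal")
  centered <- sweep(data, 2, colMeans(data))
  v_orig <- apply(centered, 2, var)
  v_proj <- apply(centered %*% basis, 2, var)
  if (any(v_orig <= 0) || any(v_proj <= 0))
    stop("phi is undefined: zero variance on an axis")
  exp(sum(log(v_proj)) - sum(log(v_orig)))
}

#' Conformity of a drug to the dominant signaling state (psi)
#'
#' `psi = PC1 / sqrt(sum_i PC_i^2)`: the drug's PC1 coordinate divided by
#' the Euclidean norm of its full coordinate vector. Ranges over
#' `[-1, 1]`; +1/-1 mean the drug's effect lies entirely along the first
#' component (one of the two anticorrelated signaling states), and the
#' value is invariant under positive rescaling of the effect vector.
#'
#' @param coords Numeric vector of PC coordinates for one drug, or a
#'   drug x component matrix (rows are drugs).
#' @return psi, or a named vector of psi per drug. All-zero coordinates
#'   give `NA` with a warning.
#' @export
psi_conformity <- function(coords) {
  f <- function(x) {
    s <- sqrt(sum(x^2))
    if (s == 0) { warning("all-zero coordinates: psi undefined"); return(NA_real_) }
    x[1] / s
  }
  if (is.matrix(coords)) apply(coords, 1, f) else f(as.numeric(coords))
}

#' Adherence of a drug's effect to PC1
#'
#' `adherence = |PC1| / sum_i PC_i^2`, exactly as conventionally printed
#' (no square root in the denominator, hence scale-dependent: halving
#' the effect vector doubles adherence). Set `normalized = TRUE` for the
#' scale-free alternative `|PC1| / sqrt(sum_i PC_i^2) = |psi|`.
#'
#' @inheritParams psi_conformity
#' @param normalized Use the scale-free variant (default `FALSE`).
#' @return Adherence, or a named vector per drug; `NA` for all-zero
#'   coordinates.
#' @export
adherence_pc1 <- function(coords, normalized = FALSE) {
  f <- function(x) {
    ss <- sum(x^2)
    if (ss == 0) return(NA_real_)
    if (normalized) abs(x[1]) / sqrt(ss) else abs(x[1]) / ss
  }
  if (is.matrix(coords)) apply(coords, 1, f) else f(as.numeric(coords))
}

#' Total drug strength
#'
#' `strength = sqrt(sum_i PC_i^2)`: the Euclidean norm of the drug's PC
#' coordinate vector — the total influence of the compound across all
#' reporters. Rotation-invariant: equals the norm of the centered effect
#' vector in pathway space.
#'
#' @inheritParams psi_conformity
#' @return Strength (>= 0), or a named vector per drug.
#' @export
drug_strength <- function(coords) {
  f <- function(x) sqrt(sum(x^2))
  if (is.matrix(coords)) apply(coords, 1, f) else f(as.numeric(coords))
}

#' Pathway-correlation strength over the time course
#'
#' Mean absolute off-diagonal pathway-pathway Pearson correlation at
#' every timepoint of a score matrix, with the Kendall rank correlation
#' between time and that strength — the trend statistic used to check
#' that drug treatments make the correlation structure more and more
#' prominent over the time course.
#'
#' @param scores A `score_matrix` (long data.frame).
#' @return List with `table` (data.frame: `time`, `mean_abs_r`) and
#'   `kendall_tau` (trend of `mean_abs_r` in time).
#' @export
correlation_timecourse <- function(scores) {
  times <- sort(unique(scores$time))
  mar <- vapply(times, function(t) {
    r <- suppressWarnings(pathway_correlations(score_slice(scores, t)))
    mean(abs(r[upper.tri(r)]), na.rm = TRUE)
  }, 0)
  tab <- data.frame(time = times, mean_abs_r = mar)
  list(table = tab,
       kendall_tau = unname(cor(times, mar, method = "kendall")))
}

#' Per-drug state metrics from a fitted PCA
#'
#' Convenience wrapper collecting PC1, psi, adherence and strength for
#' every drug in a fitted [fit_pca()] coordinate system.
#'
#' @param pca A `state_pca`.
#' @return data.frame with one row per drug.
#' @export
drug_state_metrics <- function(pca) {
  stopifnot(inherits(pca, "state_pca"))
  co <- pca$coordinates
  data.frame(drug = rownames(co),
             pc1 = co[, 1],
             psi = psi_conformity(co),
             adherence = adherence_pc1(co),
             strength = drug_strength(co),
             row.names = NULL, stringsAsFactors = FALSE)
}
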