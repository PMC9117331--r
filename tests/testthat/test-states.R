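test_that("Ward clustering reproduces a hand-computed merge structure", {
  m <- matrix(c(0, 0.1, 10, 10.1), ncol = 1,
              dimnames = list(paste0("d", 1:4), "p"))
  cl <- cluster_drugs(m, k = 2)
  expect_equal(unname(cl$labels["d1"]), unname(cl$labels["d2"]))
  expect_equal(unname(cl$labels["d3"]), unname(cl$labels["d4"]))
  expect_false(cl$labels["d1"] == cl$labels["d3"])
  # identical rows merge at height zero
  m2 <- rbind(a = c(1, 2), b = c(1, 2), c = c(5, 9))
  cl2 <- cluster_drugs(m2, k = 2)
  expect_equal(min(cl2$tree$height), 0)
  expect_error(cluster_drugs(m2, k = 5), "exceeds")
})

test_that("pathway correlations handle duplicates, NAs and zero variance", {
  set.seed(1)
  m <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  m <- cbind(m, a2 = m[, "a"])
  r <- pathway_correlations(m)
  expect_equal(r["a", "a2"], 1)
  expect_true(isSymmetric(r))
  expect_warning(pathway_correlations(cbind(m, z = rep(1, 10))),
                 "zero-variance")
  expect_error(pathway_correlations(m[1:2, ]), "3 drugs")
})

test_that("PCA handles collinear data and normalizes explained variance", {
  x <- cbind(a = 1:10, b = 2 * (1:10))
  p <- fit_pca(x)
  expect_equal(p$explained[1], 1)
  set.seed(2)
  y <- matrix(rnorm(60), 20, 3)
  py <- fit_pca(y)
  expect_equal(sum(py$explained), 1)
  expect_equal(crossprod(py$loadings), diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)
  # deterministic sign: the largest loading of each component is positive
  for (j in 1:3)
    expect_gt(py$loadings[which.max(abs(py$loadings[, j])), j], 0)
  expect_error(fit_pca(matrix(1, 5, 3)), "rank-0")
})

test_that("orientation pins PC1 to a requested direction", {
  set.seed(3)
  x <- matrix(rnorm(100), 50, 2) %*% diag(c(3, 1))
  p1 <- fit_pca(x, orient = c(1, 0))
  p2 <- fit_pca(x, orient = c(-1, 0))
  expect_gt(sum(p1$loadings[, 1] * c(1, 0)), 0)
  expect_lt(sum(p2$loadings[, 1] * c(1, 0)), 0)
  expect_equal(abs(p1$coordinates[, 1]), abs(p2$coordinates[, 1]))
})

test_that("phi equals 1 in the identity basis and det/prod in the eigenbasis", {
  set.seed(4)
  x <- matrix(rnorm(200), 50, 4) %*% matrix(rnorm(16), 4, 4)
  expect_equal(phi_metric(x, diag(4)), 1)
  own <- fit_pca(x)
  expect_equal(phi_metric(x, own),
               det(cov(x)) / prod(apply(x, 2, var)), tolerance = 1e-10)
  expect_lte(phi_metric(x, own), 1)      # Hadamard's inequality
  expect_error(phi_metric(x, diag(3)), "dimension")
  expect_error(phi_metric(x, matrix(1, 4, 4)), "orthonormal")
  expect_error(phi_metric(cbind(x, 0), diag(5)), "zero variance")
})

test_that("phi approaches 1 for isotropic data under any rotation", {
  set.seed(5)
  x <- matrix(rnorm(4000 * 3), 4000, 3)
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  expect_lt(abs(phi_metric(x, q) - 1), 0.02)
})

test_that("psi, adherence and strength follow their formulas", {
  expect_equal(psi_conformity(c(3, 4)), 0.6)
  expect_equal(psi_conformity(c(5, 0)), 1)
  expect_equal(psi_conformity(c(-5, 0)), -1)
  expect_equal(psi_conformity(2 * c(3, 4)), psi_conformity(c(3, 4)))
  expect_warning(expect_true(is.na(psi_conformity(c(0, 0)))))
  expect_equal(adherence_pc1(c(2, 0)), 0.5)
  expect_equal(adherence_pc1(c(0, 7)), 0)
  expect_equal(adherence_pc1(c(1, 0)), 1)
  expect_equal(adherence_pc1(c(3, 4), normalized = TRUE), 0.6)
  expect_equal(drug_strength(c(3, 4)), 5)
  expect_equal(drug_strength(c(0, 0)), 0)
})

test_that("strength is the rotation-invariant norm of the centered signature", {
  set.seed(6)
  x <- matrix(rnorm(80), 20, 4, dimnames = list(paste0("d", 1:20), NULL))
  p <- fit_pca(x)
  s <- drug_strength(p$coordinates)
  centered <- sweep(x, 2, colMeans(x))
  expect_equal(unname(s), unname(sqrt(rowSums(centered^2))),
               tolerance = 1e-10)
  # psi^2 <= 1 and normalized coordinates have unit norm
  psi <- psi_conformity(p$coordinates)
  expect_true(all(psi^2 <= 1 + 1e-12))
  expect_equal(unname(rowSums((p$coordinates / s)^2)), rep(1, 20),
               tolerance = 1e-10)
})

test_that("a planted state axis is recovered from a small screen", {
  des <- small_design(n_pos = 8, n_neg = 8, n_idio = 4,
                      cells_per_well = 100, seed = 77)
  sim <- simulate_screen(des)
  sc <- score_screen(sim$cells)
  m <- score_slice(sc, 48)
  u <- sim$truth$u[colnames(m)]
  pca <- fit_pca(m, orient = u)
  expect_gt(abs(sum(pca$loadings[, 1] * u)), 0.9)
  cl <- cluster_drugs(m, k = 3)
  grp <- sim$truth$drugs$group[match(rownames(m), sim$truth$drugs$drug)]
  expect_gt(mclust::adjustedRandIndex(cl$labels, grp), 0.9)
  # anticorrelated planted clusters: intercluster r negative
  r <- pathway_correlations(m)
  expect_lt(r["ERK", "p53"], -0.5)
  expect_gt(r["ERK", "p38"], 0.5)
})

test_that("drug state metrics table is coherent", {
  set.seed(8)
  x <- matrix(rnorm(60), 15, 4, dimnames = list(paste0("d", 1:15), NULL))
  met <- drug_state_metrics(fit_pca(x))
  expect_equal(nrow(met), 15)
  expect_equal(met$psi, unname(met$pc1 / met$strength))
  expect_equal(met$adherence, unname(abs(met$pc1) / met$strength^2))
})
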