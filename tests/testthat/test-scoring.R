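test_that("per-cell readouts follow the reporter type", {
  cells <- data.frame(cyto_mean = c(4, 3), nuc_mean = c(2, 0),
                      background = c(0.5, 0.5))
  expect_message(r <- per_cell_readout(cells, "ratio"), "dropped")
  expect_equal(as.numeric(r), 2)          # 4 / 2; zero-nucleus cell dropped
  expect_equal(attr(r, "dropped"), 2L)
  ni <- per_cell_readout(data.frame(nuc_mean = c(2, 0.3),
                                    background = c(0.5, 0.5)),
                         "nuclear_intensity")
  expect_equal(as.numeric(ni), c(1.5, 0))  # negative clipped at 0
  expect_equal(attr(ni, "clipped"), 1L)
  expect_error(per_cell_readout(data.frame(x = 1), "ratio"), "cyto_mean")
})

test_that("signed KS reproduces hand-enumerated cases", {
  expect_equal(signed_ks(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(signed_ks(c(1, 2, 3), c(4, 5, 6)), -1)
  expect_equal(signed_ks(c(0, 1), c(0.5, 1.5)), -0.5)
  expect_error(signed_ks(numeric(), 1:3), "nonempty")
})

test_that("KS statistic matches the brute-force ECDF oracle", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(2:50, 1); m <- sample(2:50, 1)
    x <- round(rnorm(n), sample(0:2, 1))  # rounding induces ties
    y <- round(rnorm(m, mean = runif(1, -1, 1)), sample(0:2, 1))
    D <- ks_brute(x, y)
    expect_equal(ks_statistic(x, y), D, tolerance = 1e-12)
    # the signed score is +/-D, or 0 only in the fully tied-center case
    s <- signed_ks(x, y)
    expect_true(abs(abs(s) - D) < 1e-12 || s == 0)
  }
})

test_that("signed KS is antisymmetric and monotone-invariant", {
  set.seed(7)
  for (i in 1:50) {
    x <- rnorm(30); y <- rnorm(25, 0.5)
    expect_equal(signed_ks(x, y), -signed_ks(y, x))
    g <- function(z) exp(z) + z^3   # strictly increasing
    expect_equal(signed_ks(g(x), g(y)), signed_ks(x, y))
  }
})

test_that("screen scoring groups cells and enforces the 30-cell floor", {
  spec <- rbind(
    cells_spec("c1", "DMSO", c(0, 24), "ERK", n = 60),
    cells_spec("c2", "DMSO", c(0, 24), "ERK", n = 60),
    cells_spec("w1", "drugA", c(0, 24), "ERK", n = 60, shift = 2),
    cells_spec("w2", "drugB", c(0, 24), "ERK", n = 29))
  cells <- make_cells(spec, seed = 4)
  sc <- score_screen(cells)
  a <- sc[sc$drug == "drugA" & sc$time == 24, ]
  expect_true(a$valid)
  expect_gt(a$score, 0.5)                 # planted activation, positive sign
  expect_equal(a$n_control, 120)          # DMSO wells pooled
  b <- sc[sc$drug == "drugB", ]
  expect_false(any(b$valid))              # 29 treated cells -> invalid
  expect_true(all(is.na(b$score)))
  expect_error(score_screen(cells[cells$drug != "DMSO", ]), "control")
})

test_that("planted activation grows with the effect ramp", {
  des <- small_design(n_pos = 2, n_neg = 0, n_idio = 0,
                      effect_range = c(2, 2), idio_sd = 0,
                      well_jitter_sd = 0, state_jitter_sd = 0,
                      cells_per_well = 120, seed = 31)
  sim <- simulate_screen(des)
  sc <- score_screen(sim$cells)
  # a positively-loaded KTR pathway: score positive and increasing in t
  erk <- sc[sc$drug == "D001" & sc$pathway == "ERK", ]
  erk <- erk[order(erk$time), ]
  expect_gt(erk$score[3], erk$score[2])
  expect_gt(erk$score[3], 0.15)
  # a negatively-loaded TRE pathway mirrors it
  p53 <- sc[sc$drug == "D001" & sc$pathway == "p53", ]
  expect_lt(p53$score[p53$time == 48], -0.15)
})

test_that("threshold derivation uses the fixed linear-interpolation quantile", {
  expect_equal(derive_threshold(rep(0, 30)), 0)
  grid <- seq(0.01, 0.30, length.out = 100)
  thr <- derive_threshold(grid)
  expect_equal(thr, 0.01 + 98.505 * (0.29 / 99), tolerance = 1e-12)
  expect_error(derive_threshold(rep(0.1, 5)), "at least 20")
})

test_that("control-vs-control null keeps nearly all scores under the threshold", {
  des <- small_design(n_pos = 4, n_neg = 0, n_idio = 0,
                      effect_range = c(0, 0), idio_sd = 0,
                      n_dmso_wells = 8, seed = 12)
  sim <- simulate_screen(des)
  null <- dmso_null_scores(sim$cells)
  thr <- derive_threshold(null)
  sc <- score_screen(sim$cells)
  frac_below <- mean(abs(sc$score[sc$valid]) <= thr)
  expect_gte(frac_below, 0.95)
})

test_that("active-drug calling respects validity, time and threshold", {
  spec <- rbind(
    cells_spec("c1", "DMSO", c(0, 24), "ERK", n = 60),
    cells_spec("c2", "DMSO", c(0, 24), "ERK", n = 60),
    cells_spec("w1", "hit", c(0, 24), "ERK", n = 60, shift = 3),
    cells_spec("w2", "null", c(0, 24), "ERK", n = 60))
  sc <- score_screen(make_cells(spec, seed = 8))
  expect_equal(active_drugs(sc, 0.2), "hit")
  expect_equal(active_drugs(sc, Inf), character())
  # baseline-only excess never activates: time 0 is excluded
  sc0 <- sc; sc0$score[sc0$time == 24] <- 0
  expect_equal(active_drugs(sc0, 0.2), character())
})

test_that("score slices reshape and drop incomplete pathways", {
  spec <- rbind(
    cells_spec("c1", "DMSO", 24, c("ERK", "p53"), n = 60),
    cells_spec("w1", "d1", 24, c("ERK", "p53"), n = 60),
    cells_spec("w2", "d2", 24, "ERK", n = 60))
  sc <- score_screen(make_cells(spec, seed = 2))
  m <- score_slice(sc, 24)
  expect_equal(dim(m), c(2, 2))
  expect_true(is.na(m["d2", "p53"]))
  m2 <- score_slice(sc, 24, drop_incomplete = TRUE)
  expect_equal(colnames(m2), "ERK")
})
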