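test_that("barcode panel validates its fields", {
  expect_equal(nrow(barcode_panel()$barcodes), 12)
  expect_error(barcode_panel(localizations = c("nuclear", "membrane")),
               "unknown localization")
  expect_error(barcode_panel(barcodes = data.frame(
    fluorophore = c("CFP", "CFP"),
    localization = c("nuclear", "nuclear"))), "unique")
  expect_error(barcode_panel(barcodes = data.frame(
    fluorophore = "mCherry", localization = "nuclear")),
    "unknown fluorophore")
})

test_that("barcode combination enumeration matches the panel algebra", {
  panel <- barcode_panel()
  singles <- barcode_combinations(panel, 1)
  duals <- barcode_combinations(panel, 2)
  expect_equal(nrow(singles), 20)
  expect_equal(nrow(duals), 160)
  # dual combinations never share a localization
  expect_true(all(duals$localization_1 != duals$localization_2))
  # unordered: no pair appears twice
  key <- apply(duals, 1, function(r)
    paste(sort(c(paste(r[1], r[2]), paste(r[3], r[4]))), collapse = "|"))
  expect_equal(anyDuplicated(key), 0L)
})

test_that("image generator handles the empty case", {
  set <- one_clone_set(n_cells = 0, shape = c(64, 64))
  expect_equal(nrow(set$ground_truth), 0)
  f <- set$fields[[1]]
  expect_true(all(f$cell_labels == 0))
  expect_true(all(vapply(f$channels, function(ch) all(ch == 0), TRUE)))
})

test_that("noiseless nuclear barcode emits signal only on the nucleus mask", {
  set <- one_clone_set(localization = "nuclear", n_cells = 3, noise = 0)
  f <- set$fields[[1]]
  sig <- f$channels$CFP > 0
  nuc <- f$nucleus_labels > 0
  expect_true(all(sig == (sig & nuc)))   # signal subset of nucleus pixels
  expect_gt(sum(sig), 0)
})

test_that("cytoplasmic and ER barcodes avoid the nucleus; puncta sit inside the cell", {
  for (loc in c("cytoplasmic", "er", "peroxisome")) {
    set <- one_clone_set(localization = loc, n_cells = 3, noise = 0)
    f <- set$fields[[1]]
    sig <- f$channels$CFP > 0
    expect_gt(sum(sig), 0)
    expect_true(all(f$cell_labels[sig] > 0))
    if (loc != "peroxisome")
      expect_true(!any(f$nucleus_labels[sig] > 0))
  }
})

test_that("a 4-fluorophore x 3-localization panel yields 12 clones", {
  set <- simulate_barcode_images(barcode_panel(), n_cells_per_clone = 2,
                                 image_shape = c(128, 128), noise = 0,
                                 seed = 3)
  expect_equal(length(unique(set$ground_truth$clone)), 12)
})

test_that("image generation is reproducible under a fixed seed", {
  a <- one_clone_set(n_cells = 4, seed = 9, noise = noise_params())
  b <- one_clone_set(n_cells = 4, seed = 9, noise = noise_params())
  expect_identical(a$fields[[1]]$channels, b$fields[[1]]$channels)
  expect_identical(a$ground_truth, b$ground_truth)
})

test_that("null screen yields treated and control readouts identical in law", {
  des <- small_design(effect_range = c(0, 0), idio_sd = 0,
                      idio_norm_range = c(0, 0), well_jitter_sd = 0,
                      state_jitter_sd = 0, seed = 21)
  sim <- simulate_screen(des)
  expect_true(all(abs(sim$truth$effects) == 0))
  sc <- score_screen(sim$cells)
  expect_true(all(abs(sc$score[sc$valid]) < 0.25))
  expect_lt(median(abs(sc$score[sc$valid])), 0.1)
})

test_that("opposite unit state weights give exactly antiparallel effects", {
  des <- screen_design(n_pos = 1, n_neg = 1, n_idio = 0,
                       effect_range = c(1, 1), idio_sd = 0,
                       n_dmso_wells = 2, wells_per_drug = 1,
                       timepoints = c(0, 24), cells_per_well = 5, seed = 2)
  sim <- simulate_screen(des)
  w <- sim$truth$effects[, , 2]
  expect_equal(unname(w[1, ]), unname(-w[2, ]))
})

test_that("screen generation is bit-reproducible with the seed", {
  a <- simulate_screen(small_design(seed = 33))
  b <- simulate_screen(small_design(seed = 33))
  expect_identical(a$cells, b$cells)
  expect_identical(a$truth$effects, b$truth$effects)
})

test_that("growth time course doubles exactly without noise", {
  tc <- simulate_growth_timecourse(log(2) / 24, 24, c(0, 24, 48),
                                   noise_cv = 0)
  n0 <- tc$count[tc$time == 0][1]
  expect_equal(tc$count[tc$time == 24][1], 2 * n0)
  expect_equal(tc$count[tc$time == 48][1], 4 * n0)
  expect_equal(length(unique(tc$replicate)), 2)
  expect_error(simulate_growth_timecourse(0.03, 24, c(0, 24),
                                          noise_cv = -1), "nonnegative")
})

test_that("cohort generator reproduces the reference correlation", {
  p <- 8  # surrogate protein panel size
  ref <- diag(p)
  ref[1, 2] <- ref[2, 1] <- 0.8
  rownames(ref) <- colnames(ref) <- paste0("P", 1:p)
  co <- simulate_cohort_proteomes(ref, n_samples = 1e4, seed = 4)[[1]]
  expect_equal(ncol(co), p)
  expect_equal(attr(co, "n_samples"), 1e4)
  emp <- cor(co)
  expect_lt(abs(emp[1, 2] - 0.8), 0.02)   # Fisher-z SE ~ 0.01 at n = 1e4
  off <- emp[upper.tri(emp)][-1]
  expect_lt(max(abs(off)), 0.05)          # independence elsewhere
})

test_that("non-PSD reference is rejected naming the eigenvalue", {
  bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  expect_error(simulate_cohort_proteomes(bad, 10),
               "not positive semidefinite.*eigenvalue|eigenvalue")
})
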