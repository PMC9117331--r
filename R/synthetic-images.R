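#' Define a visual-barcode panel
#'
#' A visual barcode is a fluorescent protein targeted to a specific
#' subcellular compartment; the (fluorophore, localization) pair labels the
#' clonal identity of a cell in a mixed population. The default panel
#' carries four fluorophores and five localization patterns, with the
#' twelve barcodes in routine use being the four fluorophores crossed with
#' the whole-cell, cytoplasmic and peroxisomal localizations.
#'
#' @param fluorophores Character vector of fluorophore channel names.
#' @param localizations Character vector of localization pattern names;
#'   must be a subset of `whole_cell`, `cytoplasmic`, `nuclear`,
#'   `peroxisome`, `er`.
#' @param barcodes Optional data.frame with columns `fluorophore` and
#'   `localization` selecting the (fluorophore, localization) pairs in use.
#'   Defaults to all fluorophores crossed with the whole-cell, cytoplasmic
#'   and peroxisomal localizations (12 barcodes for the default panel).
#' @return An object of class `barcode_panel`.
#' @examples
#' panel <- barcode_panel()
#' nrow(panel$barcodes)  # 12
#' @export
barcode_panel <- function(fluorophores = c("BFP", "CFP", "GFP", "YFP"),
                          localizations = c("whole_cell", "cytoplasmic",
                                            "nuclear", "peroxisome", "er"),
                          barcodes = NULL) {
  known <- c("whole_cell", "cytoplasmic", "nuclear", "peroxisome", "er")
  if (!all(localizations %in% known))
    stop("unknown localization(s): ",
         paste(setdiff(localizations, known), collapse = ", "))
  if (anyDuplicated(fluorophores) || anyDuplicated(localizations))
    stop("fluorophores and localizations must be unique")
  if (is.null(barcodes)) {
    locs <- intersect(c("whole_cell", "cytoplasmic", "peroxisome"),
                      localizations)
    barcodes <- expand.grid(fluorophore = fluorophores, localization = locs,
                            KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  }
  barcodes <- as.data.frame(barcodes, stringsAsFactors = FALSE)
  if (!all(c("fluorophore", "localization") %in% names(barcodes)))
    stop("'barcodes' needs columns 'fluorophore' and 'localization'")
  if (!all(barcodes$fluorophore %in% fluorophores))
    stop("barcode references unknown fluorophore")
  if (!all(barcodes$localization %in% localizations))
    stop("barcode references unknown localization")
  if (anyDuplicated(barcodes[c("fluorophore", "localization")]))
    stop("barcodes must be unique (fluorophore, localization) pairs")
  barcodes$clone <- paste(barcodes$fluorophore, barcodes$localization,
                          sep = "_")
  structure(list(fluorophores = fluorophores,
                 localizations = localizations,
                 barcodes = barcodes),
            class = "barcode_panel")
}

#' @export
print.barcode_panel <- function(x, ...) {
  cat("Visual barcode panel:", length(x$fluorophores), "fluorophores x",
      length(x$localizations), "localizations;",
      nrow(x$barcodes), "barcodes in use\n")
  invisible(x)
}

#' Enumerate distinguishable barcode combinations
#'
#' Exhaustively enumerates the visual barcodes that can be formed from a
#' panel when each cell carries one or two barcode proteins. With one
#' protein per cell every (fluorophore, localization) pair is a distinct
#' barcode. With two proteins per cell, the two proteins must occupy
#' distinct localizations to be resolvable in an image, while fluorophores
#' may repeat (the same color in two compartments is still distinguishable);
#' combinations are unordered. For four fluorophores and five localizations
#' this yields 20 single-protein and 160 dual-protein barcodes.
#'
#' @param panel A [barcode_panel()]. The full fluorophore x localization
#'   space of the panel is enumerated, not only the barcodes in use.
#' @param proteins_per_cell 1 or 2.
#' @return A data.frame with one row per distinguishable combination.
#' @examples
#' nrow(barcode_combinations(barcode_panel(), 2))  # 160
#' @export
barcode_combinations <- function(panel, proteins_per_cell = 1) {
  stopifnot(inherits(panel, "barcode_panel"))
  if (!proteins_per_cell %in% c(1, 2))
    stop("'proteins_per_cell' must be 1 or 2")
  singles <- expand.grid(fluorophore = panel$fluorophores,
                         localization = panel$localizations,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (proteins_per_cell == 1) return(singles)
  n <- nrow(singles)
  out <- vector("list", n * n)
  k <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      if (singles$localization[i] == singles$localization[j]) next
      k <- k + 1L
      out[[k]] <- data.frame(
        fluorophore_1 = singles$fluorophore[i],
        localization_1 = singles$localization[i],
        fluorophore_2 = singles$fluorophore[j],
        localization_2 = singles$localization[j],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out[seq_len(k)])
}

#' Imaging-noise parameters for the synthetic microscope
#'
#' Pixel values are corrupted with Poisson shot noise at a finite photon
#' budget followed by additive Gaussian read noise, on top of a uniform
#' background level. Passing `0` wherever a `noise` argument is expected
#' disables all three components.
#'
#' @param photons Expected photon count at unit intensity (shot-noise
#'   scale); larger is cleaner.
#' @param read_sd Standard deviation of additive Gaussian read noise,
#'   in intensity units on the `[0, 1]` scale.
#' @param background Uniform background intensity added to every channel.
#' @return A list of class `noise_params`.
#' @export
noise_params <- function(photons = 400, read_sd = 0.01, background = 0.03) {
  stopifnot(photons > 0, read_sd >= 0, background >= 0)
  structure(list(photons = photons, read_sd = read_sd,
                 background = background), class = "noise_params")
}

# Pixel set of an ellipse, 0-based (row, col) convention internally stored
# as 1-based matrix indices.
#' Rasterize an elliptical mask
#'
#' Utility used by the image generator: returns the logical mask of an
#' ellipse of a given pixel area, axis ratio and orientation. Exposed so
#' that bespoke geometries (e.g. deliberately touching nuclei) can be
#' composed in user code and tests.
#'
#' @param shape `c(rows, cols)` of the target image.
#' @param center `c(row, col)` center in pixels.
#' @param area Target area in pixels.
#' @param ratio Minor/major axis ratio in (0, 1].
#' @param angle Orientation in radians.
#' @return A logical matrix of dimension `shape`.
#' @export
ellipse_mask <- function(shape, center, area, ratio = 1, angle = 0) {
  stopifnot(length(shape) == 2, area > 0, ratio > 0, ratio <= 1)
  # area = pi * a * b with b = ratio * a
  a <- sqrt(area / (pi * ratio))
  b <- ratio * a
  r <- matrix(seq_len(shape[1]), shape[1], shape[2]) - center[1]
  c <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE) - center[2]
  u <- cos(angle) * r + sin(angle) * c
  v <- -sin(angle) * r + cos(angle) * c
  (u / a)^2 + (v / b)^2 <= 1
}

# Disc mask for puncta.
disc_mask <- function(shape, center, radius) {
  ellipse_mask(shape, center, pi * radius^2, ratio = 1, angle = 0)
}

# Bounding-box-local ellipse rasterization: returns row/col index ranges
# and the local logical mask (placement and rendering stay O(cell area),
# not O(image area)).
ellipse_local <- function(shape, center, a, b, angle, pad = 0) {
  ext <- a + pad + 1
  r0 <- max(1L, floor(center[1] - ext)); r1 <- min(shape[1], ceiling(center[1] + ext))
  c0 <- max(1L, floor(center[2] - ext)); c1 <- min(shape[2], ceiling(center[2] + ext))
  if (r0 > r1 || c0 > c1)
    return(list(rows = integer(), cols = integer(),
                mask = matrix(FALSE, 0, 0)))
  rr <- matrix(r0:r1, r1 - r0 + 1, c1 - c0 + 1) - center[1]
  cc <- matrix(c0:c1, r1 - r0 + 1, c1 - c0 + 1, byrow = TRUE) - center[2]
  u <- cos(angle) * rr + sin(angle) * cc
  v <- -sin(angle) * rr + cos(angle) * cc
  list(rows = r0:r1, cols = c0:c1,
       mask = (u / a)^2 + (v / b)^2 <= 1)
}

apply_noise <- function(channel, noise) {
  if (is.numeric(noise) && length(noise) == 1L && noise == 0) return(channel)
  stopifnot(inherits(noise, "noise_params"))
  x <- channel + noise$background
  x <- rpois(length(x), pmax(x, 0) * noise$photons) / noise$photons
  x <- x + rnorm(length(x), sd = noise$read_sd)
  matrix(pmin(pmax(x, 0), 1), nrow(channel), ncol(channel))
}

#' Simulate visual-barcode image sets with ground truth
#'
#' Generates, for every barcode clone in the panel, one or more synthetic
#' multi-channel fields: a nuclear-marker channel, a phase-contrast-like
#' cell-body channel (the segmentation substrate, mimicking digital phase
#' contrast), and one channel per fluorophore in the panel (only the
#' clone's own fluorophore carries signal). Cells are random ellipses of
#' 300-1200 px area with concentric elliptical nuclei at 30% of the cell
#' area; localization renderings follow the pattern vocabulary of
#' [barcode_panel()]. Poisson-Gaussian noise is added per
#' [noise_params()]. Ground-truth label maps and a per-cell table are
#' returned for training and evaluation.
#'
#' @param panel A [barcode_panel()].
#' @param n_cells_per_clone Cells to place per clone (>= 0); spread over as
#'   many fields as needed to keep the fill fraction moderate.
#' @param image_shape `c(rows, cols)`, at least 64 x 64.
#' @param noise A [noise_params()] object, or `0` for noiseless images.
#' @param seed Integer seed; the master seed fans out to per-clone child
#'   seeds.
#' @param max_fill Maximum fraction of field pixels occupied by cells.
#' @return An object of class `barcode_image_set`: a list with `fields`
#'   (each holding `clone`, named `channels`, `cell_labels`,
#'   `nucleus_labels`), `ground_truth` (per-cell data.frame), `panel`,
#'   and `skipped` (cells dropped after bounded placement retries).
#' @export
simulate_barcode_images <- function(panel, n_cells_per_clone = 220,
                                    image_shape = c(640, 640),
                                    noise = noise_params(), seed = 1,
                                    max_fill = 0.12) {
  stopifnot(inherits(panel, "barcode_panel"), n_cells_per_clone >= 0)
  if (any(image_shape < 64)) stop("'image_shape' must be at least 64 x 64")
  clones <- panel$barcodes
  seeds <- child_seeds(seed, clones$clone)
  npix <- prod(image_shape)
  mean_area <- 750
  per_field <- max(1L, floor(max_fill * npix / mean_area))
  fields <- list()
  gt <- list()
  skipped <- 0L
  for (ci in seq_len(nrow(clones))) {
    res <- with_seed(seeds[ci], {
      n_left <- n_cells_per_clone
      cl_fields <- list()
      cl_gt <- list()
      fno <- 0L
      repeat {
        n_here <- min(per_field, n_left)
        fno <- fno + 1L
        f <- render_field(clones[ci, ], panel$fluorophores, n_here,
                          image_shape, noise)
        f$field$field <- sprintf("%s_f%02d", clones$clone[ci], fno)
        cl_fields[[fno]] <- f$field
        if (nrow(f$cells) > 0) {
          f$cells$field <- f$field$field
          cl_gt[[fno]] <- f$cells
        }
        skipped <- skipped + f$skipped
        n_left <- n_left - n_here
        if (n_left <= 0L) break
      }
      list(fields = cl_fields, gt = cl_gt)
    })
    fields <- c(fields, res$fields)
    gt <- c(gt, res$gt)
  }
  ground_truth <- if (length(gt)) do.call(rbind, gt) else
    data.frame(field = character(), clone = character(),
               fluorophore = character(), localization = character(),
               label = integer(), area = numeric())
  rownames(ground_truth) <- NULL
  if (skipped > 0)
    message(skipped, " cell placement(s) skipped after bounded retries")
  structure(list(fields = fields, ground_truth = ground_truth,
                 panel = panel, skipped = skipped, seed = seed),
            class = "barcode_image_set")
}

# One synthetic field for one clone. Returns channels, labels, ground truth.
render_field <- function(clone_row, fluorophores, n_cells, shape, noise) {
  cell_lab <- matrix(0L, shape[1], shape[2])
  nuc_lab <- matrix(0L, shape[1], shape[2])
  chans <- c("nuclear", "dpc", fluorophores)
  channels <- lapply(chans, function(x) matrix(0, shape[1], shape[2]))
  names(channels) <- chans
  cells <- list()
  skipped <- 0L
  lab <- 0L
  margin <- 22
  add_local <- function(ch, loc, val) {
    channels[[ch]][loc$rows, loc$cols] <<-
      channels[[ch]][loc$rows, loc$cols] + val
    invisible(NULL)
  }
  for (i in seq_len(n_cells)) {
    placed <- FALSE
    for (try in seq_len(40L)) {
      ctr <- c(runif(1, margin, shape[1] - margin),
               runif(1, margin, shape[2] - margin))
      area <- runif(1, 300, 1200)
      ratio <- runif(1, 0.55, 0.95)
      ang <- runif(1, 0, pi)
      a <- sqrt(area / (pi * ratio)); bax <- ratio * a
      loc <- ellipse_local(shape, ctr, a, bax, ang, pad = 4)
      cmask <- loc$mask
      if (!any(cmask) ||
          any(cell_lab[loc$rows, loc$cols][cmask] != 0L)) next
      # concentric nucleus, 30% of cell area, small center jitter
      nctr <- ctr + runif(2, -2, 2)
      an <- sqrt(0.30) * a; bn <- sqrt(0.30) * bax
      nloc <- ellipse_local(shape, nctr, an, bn, ang)
      nmask_full <- matrix(FALSE, length(loc$rows), length(loc$cols))
      ri <- match(nloc$rows, loc$rows); ci <- match(nloc$cols, loc$cols)
      nmask_full[ri[!is.na(ri)], ci[!is.na(ci)]] <-
        nloc$mask[!is.na(ri), !is.na(ci)]
      nmask <- nmask_full & cmask
      if (sum(nmask) < 10) next
      lab <- lab + 1L
      slab <- cell_lab[loc$rows, loc$cols]; slab[cmask] <- lab
      cell_lab[loc$rows, loc$cols] <- slab
      snl <- nuc_lab[loc$rows, loc$cols]; snl[nmask] <- lab
      nuc_lab[loc$rows, loc$cols] <- snl
      b <- min(0.85, rlnorm(1, log(0.45), 0.18))
      nb <- min(0.9, rlnorm(1, log(0.55), 0.15))
      add_local("nuclear", loc, nb * nmask)
      add_local("dpc", loc, 0.5 * cmask)
      fch <- clone_row$fluorophore
      sig <- switch(clone_row$localization,
        whole_cell  = b * cmask,
        cytoplasmic = b * (cmask & !nmask),
        nuclear     = b * nmask,
        er = {
          # geometric annulus: nucleus ellipse grown by the ring width
          eloc <- ellipse_local(shape, nctr, an + 3, bn + 3, ang)
          emask <- matrix(FALSE, length(loc$rows), length(loc$cols))
          eri <- match(eloc$rows, loc$rows); eci <- match(eloc$cols, loc$cols)
          emask[eri[!is.na(eri)], eci[!is.na(eci)]] <-
            eloc$mask[!is.na(eri), !is.na(eci)]
          1.5 * b * (emask & cmask & !nmask)
        },
        peroxisome = {
          cyto_idx <- which(cmask & !nmask)
          sig <- matrix(0, length(loc$rows), length(loc$cols))
          if (length(cyto_idx)) {
            n_punc <- sample(5:20, 1L)
            pick <- sample(cyto_idx, min(n_punc, length(cyto_idx)))
            nr <- length(loc$rows)
            for (idx in pick) {
              pr <- (idx - 1L) %% nr + 1L; pc <- (idx - 1L) %/% nr + 1L
              rad <- sample(1:2, 1L)
              pr_rng <- max(1, pr - rad):min(nr, pr + rad)
              pc_rng <- max(1, pc - rad):min(length(loc$cols), pc + rad)
              dd <- outer((pr_rng - pr)^2, (pc_rng - pc)^2, "+") <= rad^2
              sig[pr_rng, pc_rng][dd] <- 2 * b
            }
          }
          sig * cmask
        },
        stop("unknown localization: ", clone_row$localization))
      add_local(fch, loc, sig)
      cells[[lab]] <- data.frame(clone = clone_row$clone,
                                 fluorophore = clone_row$fluorophore,
                                 localization = clone_row$localization,
                                 label = lab, area = sum(cmask),
                                 stringsAsFactors = FALSE)
      placed <- TRUE
      break
    }
    if (!placed) skipped <- skipped + 1L
  }
  channels <- lapply(channels, apply_noise, noise = noise)
  list(field = list(clone = clone_row$clone, channels = channels,
                    cell_labels = cell_lab, nucleus_labels = nuc_lab),
       cells = if (length(cells)) do.call(rbind, cells) else
         data.frame(clone = character(), fluorophore = character(),
                    localization = character(), label = integer(),
                    area = numeric()),
       skipped = skipped)
}

#' Write a synthetic image set to multi-page TIFF files
#'
#' One 16-bit multi-page TIFF per field (one page per channel, channel
#' names recorded both as per-page TIFF descriptions and in a
#' `channels.json` sidecar), plus 16-bit label-map TIFFs for cells and
#' nuclei.
#'
#' @param set A `barcode_image_set`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_image_set <- function(set, dir) {
  stopifnot(inherits(set, "barcode_image_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  for (f in set$fields) {
    base <- file.path(dir, f$field)
    pages <- lapply(names(f$channels), function(nm) {
      m <- pmin(pmax(f$channels[[nm]], 0), 1)
      attr(m, "description") <- nm
      m
    })
    tiff::writeTIFF(pages, paste0(base, ".tif"), bits.per.sample = 16L)
    tiff::writeTIFF(f$cell_labels / 65535, paste0(base, "_cells.tif"),
                    bits.per.sample = 16L)
    tiff::writeTIFF(f$nucleus_labels / 65535, paste0(base, "_nuclei.tif"),
                    bits.per.sample = 16L)
    written <- c(written, paste0(base, ".tif"))
  }
  jsonlite::write_json(lapply(set$fields, function(f) names(f$channels)),
                       file.path(dir, "channels.json"))
  utils::write.csv(set$ground_truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(written)
}
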