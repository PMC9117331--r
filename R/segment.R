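#' Segmentation parameters
#'
#' @param nucleus_sigma Gaussian smoothing sigma (px) before nucleus
#'   thresholding.
#' @param nucleus_offset Additive offset on the automatic (Otsu)
#'   threshold.
#' @param watershed_tolerance Minimum object-depth tolerance of the
#'   distance-transform watershed that splits touching nuclei.
#' @param min_nucleus_area Nuclei smaller than this (px) are discarded.
#' @param min_cell_area Cells smaller than this (px) are discarded.
#' @param ring_width Perinuclear ring width (px).
#' @param bg_inner,bg_outer Background annulus: ring from `bg_inner` to
#'   `bg_outer` px outside the cell, excluding all cells.
#' @return List of class `seg_params`.
#' @export
seg_params <- function(nucleus_sigma = 2, nucleus_offset = 0,
                       watershed_tolerance = 1, min_nucleus_area = 20,
                       min_cell_area = 60, ring_width = 3,
                       bg_inner = 2, bg_outer = 5) {
  structure(as.list(environment()), class = "seg_params")
}

empty_segmentation <- function(shape) {
  z <- matrix(0L, shape[1], shape[2])
  structure(list(nucleus_labels = z, cell_labels = z,
                 cytoplasm_labels = z, ring_labels = z,
                 background_labels = z, n_cells = 0L,
                 dropped = 0L),
            class = "cell_segmentation")
}

#' Segment nuclei and cells from a nuclear-marker and a body channel
#'
#' Nuclei are detected on the smoothed nuclear-marker channel by
#' automatic (Otsu) thresholding followed by a distance-transform
#' watershed that splits touching nuclei. Cells are grown from the
#' nucleus seeds over the cell-body channel (Voronoi-like seeded region
#' growing restricted to the body foreground). Per-cell tertiary
#' compartments are derived: cytoplasm (cell minus nucleus minus
#' perinuclear ring), a perinuclear ring around the nucleus, and a
#' cell-specific background annulus 2-5 px outside the cell excluding
#' all cells. The procedure is deterministic.
#'
#' @param nuclear_channel,body_channel Numeric matrices of the same
#'   shape with nonnegative intensities.
#' @param params A [seg_params()] list.
#' @return Object of class `cell_segmentation` with integer label maps
#'   `nucleus_labels`, `cell_labels`, `cytoplasm_labels`, `ring_labels`,
#'   `background_labels` (label 0 = background everywhere), `n_cells`,
#'   and `dropped` (objects removed by the size filters).
#' @export
segment_cells <- function(nuclear_channel, body_channel,
                          params = seg_params()) {
  stopifnot(inherits(params, "seg_params"))
  nuc <- as.matrix(nuclear_channel); body <- as.matrix(body_channel)
  if (!identical(dim(nuc), dim(body)))
    stop("channel shapes differ")
  if (min(nuc) < 0 || min(body) < 0)
    stop("intensities must be nonnegative")
  rng <- range(nuc)
  if (rng[1] == rng[2]) {
    if (rng[1] > 0) stop("all-saturated nuclear channel")
    return(empty_segmentation(dim(nuc)))
  }
  sm <- EBImage::gblur(nuc, sigma = params$nucleus_sigma)
  thr <- tryCatch(EBImage::otsu(EBImage::Image(sm), range = range(sm)),
                  error = function(e) mean(range(sm)))
  nmask <- sm > (thr + params$nucleus_offset)
  if (!any(nmask)) return(empty_segmentation(dim(nuc)))
  nmask <- EBImage::fillHull(nmask)
  dm <- EBImage::distmap(nmask)
  nlab <- EBImage::imageData(EBImage::watershed(dm, tolerance =
                                                  params$watershed_tolerance))
  # size filter on nuclei
  tab <- tabulate(nlab[nlab > 0])
  small <- which(tab > 0 & tab < params$min_nucleus_area)
  dropped <- length(small)
  if (length(small)) nlab[nlab %in% small] <- 0L
  if (!any(nlab > 0)) return(empty_segmentation(dim(nuc)))

  bsm <- EBImage::gblur(body, sigma = params$nucleus_sigma)
  bthr <- tryCatch(EBImage::otsu(EBImage::Image(bsm), range = range(bsm)),
                   error = function(e) mean(range(bsm)))
  bmask <- bsm > bthr | nlab > 0
  clab <- EBImage::imageData(EBImage::propagate(bsm, seeds = nlab,
                                                mask = bmask, lambda = 1e-4))
  # size filter on cells (removes nucleus too)
  ctab <- tabulate(clab[clab > 0])
  csmall <- which(ctab > 0 & ctab < params$min_cell_area)
  dropped <- dropped + length(csmall)
  if (length(csmall)) {
    clab[clab %in% csmall] <- 0L
    nlab[nlab %in% csmall] <- 0L
  }
  # relabel 1..n consecutively
  ids <- sort(unique(clab[clab > 0]))
  if (length(ids) == 0L) return(empty_segmentation(dim(nuc)))
  remap <- integer(max(ids)); remap[ids] <- seq_along(ids)
  clab[clab > 0] <- remap[clab[clab > 0]]
  nlab[nlab > 0] <- remap[nlab[nlab > 0]]
  nlab[nlab > 0 & clab == 0] <- 0L
  nlab <- nlab * (clab == nlab | nlab == 0)  # keep nucleus inside its cell
  storage.mode(clab) <- "integer"; storage.mode(nlab) <- "integer"

  brush <- function(r) EBImage::makeBrush(2 * r + 1, shape = "disc")
  # perinuclear ring: dilated nucleus within its own cell, minus nucleus
  ndil <- EBImage::imageData(EBImage::dilate(nlab, brush(params$ring_width)))
  ring <- ndil
  ring[!(ndil > 0 & nlab == 0 & clab == ndil)] <- 0L
  # cytoplasm: cell minus nucleus minus ring (disjoint compartments)
  cyto <- clab
  cyto[nlab > 0 | ring > 0] <- 0L
  # background annulus: 2-5 px outside the cell, excluding all cells
  douter <- EBImage::imageData(EBImage::dilate(clab, brush(params$bg_outer)))
  dinner <- EBImage::imageData(EBImage::dilate(clab, brush(params$bg_inner)))
  bg <- douter
  bg[!(douter > 0 & dinner == 0 & clab == 0)] <- 0L
  storage.mode(ring) <- "integer"; storage.mode(cyto) <- "integer"
  storage.mode(bg) <- "integer"
  structure(list(nucleus_labels = nlab, cell_labels = clab,
                 cytoplasm_labels = cyto, ring_labels = ring,
                 background_labels = bg,
                 n_cells = length(ids), dropped = dropped),
            class = "cell_segmentation")
}

#' @export
print.cell_segmentation <- function(x, ...) {
  cat("Cell segmentation:", x$n_cells, "cells (", x$dropped,
      "object(s) dropped by size filters )\n")
  invisible(x)
}
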