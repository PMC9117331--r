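## Cytological profiling: per-cell intensity / texture / shape features.

# Align a computeFeatures result to n cells. Rows are keyed by label via
# rownames when present, else by position 1..nrow.
align_features <- function(f, n, prefix) {
  if (is.null(f) || length(f) == 0L)
    return(matrix(NA_real_, n, 0))
  f <- as.matrix(f)
  out <- matrix(NA_real_, n, ncol(f),
                dimnames = list(NULL, paste(prefix, colnames(f), sep = ".")))
  idx <- if (!is.null(rownames(f))) as.integer(rownames(f)) else seq_len(nrow(f))
  ok <- !is.na(idx) & idx >= 1 & idx <= n
  out[idx[ok], ] <- f[ok, , drop = FALSE]
  out
}

# Per-label Pearson correlation between two intensity images, computed
# from label-wise sufficient statistics.
label_correlation <- function(labels, a, b, n) {
  sel <- labels > 0
  l <- labels[sel]; x <- a[sel]; y <- b[sel]
  cnt <- tabulate(l, n)
  sx <- rowsum_vec(x, l, n);  sy <- rowsum_vec(y, l, n)
  sxx <- rowsum_vec(x * x, l, n); syy <- rowsum_vec(y * y, l, n)
  sxy <- rowsum_vec(x * y, l, n)
  num <- sxy - sx * sy / cnt
  den <- sqrt(pmax(sxx - sx^2 / cnt, 0) * pmax(syy - sy^2 / cnt, 0))
  r <- ifelse(cnt > 2 & den > 0, num / den, NA_real_)
  r
}

rowsum_vec <- function(x, g, n) {
  out <- numeric(n)
  rs <- rowsum(x, g)
  out[as.integer(rownames(rs))] <- rs[, 1]
  out
}

#' Extract a cytological profile per segmented cell
#'
#' Deterministic per-cell feature vectors: intensity statistics (mean,
#' sd, mad, quantiles) for every compartment (nucleus, cell, cytoplasm,
#' perinuclear ring) in every channel; integrated intensities; texture
#' (Haralick co-occurrence summaries over the cell mask) per channel;
#' shape and moment descriptors of nucleus and cell; the per-channel
#' similarity-to-nucleus feature (within-cell Pearson correlation of the
#' channel with the nuclear marker); per-channel nucleus/cytoplasm mean
#' ratios; and background-corrected nuclear means using the cell-specific
#' background annulus. With four or more channels the profile exceeds
#' 200 features. Cells smaller than `min_px` are dropped (logged via
#' the `dropped` attribute); remaining missing values (e.g. empty
#' compartments) are imputed with the column median.
#'
#' @param seg A `cell_segmentation` from [segment_cells()].
#' @param channels Named list of intensity matrices (must include the
#'   channel named `nuclear` for the similarity feature).
#' @param min_px Minimum cell area in pixels (default 10).
#' @return data.frame of class `cell_features`, one row per retained
#'   cell, first column `label`; attribute `dropped` counts removed
#'   cells.
#' @export
extract_features <- function(seg, channels, min_px = 10) {
  stopifnot(inherits(seg, "cell_segmentation"), is.list(channels))
  n <- seg$n_cells
  if (n == 0L) {
    out <- data.frame(label = integer())
    class(out) <- c("cell_features", "data.frame")
    attr(out, "dropped") <- 0L
    return(out)
  }
  for (ch in channels)
    if (!identical(dim(as.matrix(ch)), dim(seg$cell_labels)))
      stop("channel shape does not match the segmentation")
  comps <- list(nuc = seg$nucleus_labels, cell = seg$cell_labels,
                cyto = seg$cytoplasm_labels, ring = seg$ring_labels)
  areas <- lapply(comps, function(l) tabulate(l[l > 0], n))
  blocks <- list(label = matrix(seq_len(n), ncol = 1,
                                dimnames = list(NULL, "label")))
  for (ch_name in names(channels)) {
    ref <- as.matrix(channels[[ch_name]])
    for (comp_name in names(comps)) {
      f <- suppressWarnings(
        EBImage::computeFeatures.basic(comps[[comp_name]], ref))
      blk <- align_features(f, n, paste(comp_name, ch_name, sep = "."))
      # integrated intensity = mean * area
      if (ncol(blk)) {
        integ <- blk[, 1] * areas[[comp_name]]
        blk <- cbind(blk, integ)
        colnames(blk)[ncol(blk)] <-
          paste(comp_name, ch_name, "b.integrated", sep = ".")
      }
      blocks[[length(blocks) + 1L]] <- blk
    }
    th <- suppressWarnings(
      EBImage::computeFeatures.haralick(seg$cell_labels, ref))
    blocks[[length(blocks) + 1L]] <-
      align_features(th, n, paste("cell", ch_name, sep = "."))
  }
  for (comp_name in c("nuc", "cell")) {
    fs <- suppressWarnings(EBImage::computeFeatures.shape(comps[[comp_name]]))
    blocks[[length(blocks) + 1L]] <- align_features(fs, n, comp_name)
    fm <- suppressWarnings(EBImage::computeFeatures.moment(comps[[comp_name]]))
    blocks[[length(blocks) + 1L]] <- align_features(fm, n, comp_name)
  }
  x <- do.call(cbind, blocks)
  x <- as.data.frame(x)
  # nucleus/cell area ratio
  x$shape.nc_area_ratio <- areas$nuc / pmax(areas$cell, 1)
  # similarity-to-nucleus, nucleus/cytoplasm ratio, bg-corrected nucleus
  if ("nuclear" %in% names(channels)) {
    nuc_ref <- as.matrix(channels$nuclear)
    for (ch_name in setdiff(names(channels), "nuclear")) {
      ref <- as.matrix(channels[[ch_name]])
      x[[paste0("sim.", ch_name)]] <-
        label_correlation(seg$cell_labels, ref, nuc_ref, n)
    }
  }
  for (ch_name in names(channels)) {
    nm <- x[[paste("nuc", ch_name, "b.mean", sep = ".")]]
    cm <- x[[paste("cyto", ch_name, "b.mean", sep = ".")]]
    x[[paste0("ratio.nc.", ch_name)]] <- nm / pmax(cm, 1e-6)
    bgm <- suppressWarnings(
      EBImage::computeFeatures.basic(seg$background_labels,
                                     as.matrix(channels[[ch_name]])))
    bgm <- align_features(bgm, n, "bg")
    if (ncol(bgm))
      x[[paste0("bgcorr.nuc.", ch_name)]] <- pmax(nm - bgm[, "bg.b.mean"], 0)
  }
  keep <- areas$cell >= min_px
  dropped <- sum(!keep)
  if (dropped) message(dropped, " cell(s) below ", min_px, " px dropped")
  x <- x[keep, , drop = FALSE]
  # impute any remaining missing values with the column median
  for (j in seq_along(x)) {
    bad <- !is.finite(x[[j]])
    if (any(bad)) {
      med <- median(x[[j]][!bad])
      x[[j]][bad] <- if (is.finite(med)) med else 0
    }
  }
  rownames(x) <- NULL
  class(x) <- c("cell_features", "data.frame")
  attr(x, "dropped") <- dropped
  x
}

#' Extract features for every field of a synthetic image set
#'
#' Runs [segment_cells()] (nuclear marker + body channel) and
#' [extract_features()] on each field and matches segmented cells to
#' ground-truth clone labels by majority overlap with the true label
#' map.
#'
#' @param set A `barcode_image_set` from [simulate_barcode_images()].
#' @param params [seg_params()].
#' @param body_channel Name of the channel used as segmentation body
#'   (default `"dpc"`).
#' @return data.frame: columns `field`, `clone` (matched truth, `NA` if
#'   unmatched) plus all feature columns.
#' @export
profile_image_set <- function(set, params = seg_params(),
                              body_channel = "dpc") {
  stopifnot(inherits(set, "barcode_image_set"))
  out <- vector("list", length(set$fields))
  for (i in seq_along(set$fields)) {
    f <- set$fields[[i]]
    seg <- segment_cells(f$channels$nuclear, f$channels[[body_channel]],
                         params)
    if (seg$n_cells == 0L) next
    feats <- extract_features(seg, f$channels)
    if (nrow(feats) == 0L) next
    clone <- vapply(feats$label, function(lab) {
      px <- f$cell_labels[seg$cell_labels == lab]
      px <- px[px > 0]
      if (!length(px)) return(NA_character_)
      f$clone
    }, "")
    out[[i]] <- cbind(data.frame(field = f$field %||% paste0("f", i),
                                 clone = clone, stringsAsFactors = FALSE),
                      feats)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) stop("no cells profiled")
  do.call(rbind, out)
}
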