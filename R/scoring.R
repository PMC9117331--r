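#' Signed two-sample Kolmogorov-Smirnov activity score
#'
#' The score is the two-sample KS statistic `D` (the supremum of the
#' absolute difference between the two empirical CDFs) given the sign of
#' the treated-versus-control location shift: `+1` if the treated median
#' exceeds the control median, `-1` if it is lower; on a median tie the
#' sign of the mean difference is used, and `0` if that also ties. The
#' score ranges from -1 (maximal inactivation) to +1 (maximal activation)
#' and is invariant under any strictly increasing transform applied to
#' both samples.
#'
#' @param treated,control Nonempty numeric vectors of per-cell readouts.
#' @return A single score in `[-1, 1]`.
#' @examples
#' signed_ks(c(1, 2, 3), c(4, 5, 6))  # -1: fully separated, lower
#' @export
signed_ks <- function(treated, control) {
  treated <- as.numeric(treated); control <- as.numeric(control)
  treated <- treated[!is.na(treated)]; control <- control[!is.na(control)]
  if (length(treated) == 0L || length(control) == 0L)
    stop("both samples must be nonempty")
  D <- ks_statistic(treated, control)
  # order-statistic (non-interpolating) median: keeps the sign, like D
  # itself, invariant under strictly increasing transforms of both samples
  med <- function(z) quantile(z, 0.5, type = 1, names = FALSE)
  s <- sign(med(treated) - med(control))
  if (s == 0) s <- sign(mean(treated) - mean(control))
  s * D
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' The supremum of the absolute difference between the two empirical
#' CDFs, computed by a merged-sort scan with exact tie handling. This is
#' the magnitude of [signed_ks()] (whose sign can be 0 when both the
#' medians and the means of the samples tie exactly).
#'
#' @param x,y Nonempty numeric vectors.
#' @return The KS statistic `D` in `[0, 1]`.
#' @export
ks_statistic <- function(x, y) {
  n <- length(x); m <- length(y)
  w <- c(x, y)
  o <- order(w)
  z <- cumsum(ifelse(o <= n, 1 / n, -1 / m))
  ws <- w[o]
  # sup over distinct values: take the cumulative difference at the last
  # occurrence of each tied value
  keep <- c(diff(ws) != 0, TRUE)
  max(abs(z[keep]))
}

#' Per-cell reporter readout
#'
#' Computes the scalar readout a reporter type is scored on: for
#' translocation (KTR) reporters the cytoplasm/nucleus mean-intensity
#' ratio; for transcription (TRE) reporters the mean nuclear intensity
#' after subtracting the cell-specific background. Cells with zero
#' nuclear mean in ratio mode are dropped (with a message); negative
#' background-subtracted intensities are clipped at 0 and counted in the
#' `clipped` attribute.
#'
#' @param cells data.frame with columns `cyto_mean`, `nuc_mean` and
#'   (for `nuclear_intensity` mode) `background`.
#' @param mode `"ratio"` or `"nuclear_intensity"`.
#' @return Numeric vector of readouts, one per retained row; attributes
#'   `dropped` (row indices removed) and `clipped` (count clipped at 0).
#' @export
per_cell_readout <- function(cells, mode = c("ratio", "nuclear_intensity")) {
  mode <- match.arg(mode)
  if (mode == "ratio") {
    if (!all(c("cyto_mean", "nuc_mean") %in% names(cells)))
      stop("ratio mode needs columns 'cyto_mean' and 'nuc_mean'")
    bad <- which(cells$nuc_mean == 0)
    if (length(bad))
      message(length(bad), " cell(s) with zero nuclear mean dropped")
    keep <- setdiff(seq_len(nrow(cells)), bad)
    out <- cells$cyto_mean[keep] / cells$nuc_mean[keep]
    attr(out, "dropped") <- bad
    attr(out, "clipped") <- 0L
  } else {
    if (!all(c("nuc_mean", "background") %in% names(cells)))
      stop("nuclear_intensity mode needs columns 'nuc_mean' and 'background'")
    out <- cells$nuc_mean - cells$background
    n_clip <- sum(out < 0)
    out <- pmax(out, 0)
    attr(out, "dropped") <- integer()
    attr(out, "clipped") <- n_clip
  }
  out
}

# Pick the mode-appropriate readout column from a simulated/parsed cell
# table (columns readout_ratio / readout_nuclear).
readout_values <- function(cells) {
  ifelse(cells$mode == "ratio", cells$readout_ratio, cells$readout_nuclear)
}

#' Score a pooled screen: drug x pathway x time activity scores
#'
#' Groups cells by (drug, pathway, timepoint), scores each treated group
#' against the pooled time-matched DMSO cells of the same clone with
#' [signed_ks()], and marks a score invalid when either side has fewer
#' than `min_cells` cells. KTR clones are scored on the
#' cytoplasm/nucleus ratio, TRE clones on the background-subtracted
#' nuclear intensity.
#'
#' @param cells data.frame with columns `well`, `drug`, `time`, `pathway`
#'   (clone), `mode`, and readout columns `readout_ratio` /
#'   `readout_nuclear` (as produced by [simulate_screen()] or assembled
#'   via [per_cell_readout()]).
#' @param control Label identifying control wells in `drug`
#'   (default `"DMSO"`).
#' @param min_cells Minimum cells per group for a valid score (default
#'   30).
#' @return Long data.frame of class `score_matrix`: columns `drug`,
#'   `pathway`, `time`, `score`, `n_treated`, `n_control`, `valid`.
#'   `score` is `NA` where invalid.
#' @export
score_screen <- function(cells, control = "DMSO", min_cells = 30) {
  req <- c("drug", "time", "pathway", "mode")
  if (!all(req %in% names(cells)))
    stop("missing columns: ", paste(setdiff(req, names(cells)), collapse = ", "))
  cells$.readout <- readout_values(cells)
  is_ctrl <- cells$drug == control
  if (!any(is_ctrl)) stop("no control wells labeled '", control, "' found")
  key <- function(p, t) paste(p, t, sep = "\r")
  ctrl_split <- split(cells$.readout[is_ctrl],
                      key(cells$pathway[is_ctrl], cells$time[is_ctrl]))
  tr <- cells[!is_ctrl, , drop = FALSE]
  gkey <- paste(tr$drug, tr$pathway, tr$time, sep = "\r")
  groups <- split(tr$.readout, gkey)
  info <- do.call(rbind, strsplit(names(groups), "\r", fixed = TRUE))
  out <- data.frame(drug = info[, 1], pathway = info[, 2],
                    time = as.numeric(info[, 3]),
                    score = NA_real_,
                    n_treated = lengths(groups),
                    n_control = 0L, valid = FALSE,
                    stringsAsFactors = FALSE)
  missing_ctrl <- FALSE
  for (i in seq_along(groups)) {
    ctl <- ctrl_split[[key(out$pathway[i], out$time[i])]]
    if (is.null(ctl)) { missing_ctrl <- TRUE; next }
    out$n_control[i] <- length(ctl)
    if (out$n_treated[i] >= min_cells && length(ctl) >= min_cells) {
      out$score[i] <- signed_ks(groups[[i]], ctl)
      out$valid[i] <- TRUE
    }
  }
  if (missing_ctrl)
    warning("timepoints without control cells: scores there are invalid")
  out <- out[order(out$drug, out$pathway, out$time), ]
  rownames(out) <- NULL
  class(out) <- c("score_matrix", "data.frame")
  out
}

#' Reshape a long score matrix to a drug x pathway matrix at one timepoint
#'
#' @param scores A `score_matrix` (long data.frame).
#' @param time Timepoint to slice.
#' @param drop_incomplete Drop pathways with any missing value
#'   (mirrors discarding a reporter that was not measured for all drugs).
#' @return Numeric drug x pathway matrix.
#' @export
score_slice <- function(scores, time, drop_incomplete = FALSE) {
  s <- scores[scores$time == time, , drop = FALSE]
  if (nrow(s) == 0L) stop("no scores at time ", time)
  drugs <- sort(unique(s$drug)); paths <- sort(unique(s$pathway))
  m <- matrix(NA_real_, length(drugs), length(paths),
              dimnames = list(drugs, paths))
  m[cbind(match(s$drug, drugs), match(s$pathway, paths))] <-
    ifelse(s$valid, s$score, NA_real_)
  if (drop_incomplete) m <- m[, colSums(is.na(m)) == 0, drop = FALSE]
  m
}

#' Null activity scores from control wells
#'
#' Scores every control well against the pool of the remaining control
#' wells, per clone and timepoint — the null distribution used to derive
#' the activity-score significance threshold.
#'
#' @inheritParams score_screen
#' @return data.frame with columns `well`, `pathway`, `time`, `score`.
#' @export
dmso_null_scores <- function(cells, control = "DMSO", min_cells = 30) {
  cells$.readout <- readout_values(cells)
  ctl <- cells[cells$drug == control, , drop = FALSE]
  if (nrow(ctl) == 0L) stop("no control wells labeled '", control, "'")
  out <- list(); k <- 0L
  for (t in unique(ctl$time)) {
    for (p in unique(ctl$pathway)) {
      sub <- ctl[ctl$time == t & ctl$pathway == p, , drop = FALSE]
      wells <- unique(sub$well)
      if (length(wells) < 2L) next
      for (w in wells) {
        a <- sub$.readout[sub$well == w]
        b <- sub$.readout[sub$well != w]
        if (length(a) < min_cells || length(b) < min_cells) next
        k <- k + 1L
        out[[k]] <- data.frame(well = w, pathway = p, time = t,
                               score = signed_ks(a, b),
                               stringsAsFactors = FALSE)
      }
    }
  }
  if (k == 0L) stop("no control-vs-control scores could be computed")
  do.call(rbind, out)
}

#' Derive the activity-score significance threshold from control scores
#'
#' The threshold is the 99.5th percentile of the absolute
#' control-versus-control scores (the extreme half-percent tail of the
#' null), computed with R's default linear-interpolation quantile (type
#' 7). The conventional fallback when derivation is skipped is 0.2.
#'
#' @param dmso_scores Numeric vector of control-vs-control scores (or the
#'   data.frame from [dmso_null_scores()]).
#' @param min_scores Minimum number of null scores required (default 20).
#' @return The threshold (single number).
#' @export
derive_threshold <- function(dmso_scores, min_scores = 20) {
  if (is.data.frame(dmso_scores)) dmso_scores <- dmso_scores$score
  dmso_scores <- dmso_scores[!is.na(dmso_scores)]
  if (length(dmso_scores) < min_scores)
    stop("need at least ", min_scores, " control scores, got ",
         length(dmso_scores))
  unname(quantile(abs(dmso_scores), 0.995, type = 7))
}

#' Drugs with significant activity on any pathway
#'
#' A drug is called active when any valid score at a post-treatment
#' timepoint exceeds the threshold in absolute value.
#'
#' @param scores A `score_matrix`.
#' @param threshold Activity threshold (e.g. from [derive_threshold()];
#'   conventionally 0.2).
#' @return Character vector of active drug names.
#' @export
active_drugs <- function(scores, threshold = 0.2) {
  hit <- scores$valid & scores$time > 0 & abs(scores$score) > threshold
  sort(unique(scores$drug[hit %in% TRUE]))
}
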