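#' Fit an exponential proliferation model
#'
#' Log-linear least squares of `ln N(t)` over all replicate points
#' jointly: `N(t) = N0 * exp(alpha * t)`, with cell-cycle length
#' `tau = ln(2) / alpha`. Nonpositive counts are dropped with a warning;
#' a nonpositive division-rate estimate reports `tau = NA` with a flag.
#'
#' @param tc data.frame with columns `time`, `count` (and optionally
#'   `replicate`), e.g. from [simulate_growth_timecourse()].
#' @return List with `alpha` (1/h), `tau` (h or `NA`), `n_points`, and
#'   `flag` (`"ok"` or `"nonpositive_rate"`).
#' @export
fit_division <- function(tc) {
  stopifnot(all(c("time", "count") %in% names(tc)))
  bad <- !is.finite(tc$count) | tc$count <= 0
  if (any(bad)) {
    warning(sum(bad), " nonpositive count(s) dropped")
    tc <- tc[!bad, , drop = FALSE]
  }
  if (length(unique(tc$time)) < 3)
    stop("need positive counts at >= 3 timepoints")
  fit <- lm(log(count) ~ time, data = tc)
  alpha <- unname(coef(fit)["time"])
  if (alpha <= 0)
    return(list(alpha = alpha, tau = NA_real_, n_points = nrow(tc),
                flag = "nonpositive_rate"))
  list(alpha = alpha, tau = log(2) / alpha, n_points = nrow(tc),
       flag = "ok")
}

#' Fit the per-cell mass accumulation (growth) rate
#'
#' Mean per-cell mass is `m(t) = M(t) / N(t)`; its log-slope plus the
#' division rate gives the total per-cell mass synthesis rate in the
#' exponential steady state: `gamma = d ln m / dt + alpha`. In balanced
#' growth (`m` constant), `gamma = alpha`.
#'
#' @param tc data.frame with columns `time`, `count`, `mass`.
#' @return List with `gamma` (1/h), `alpha`, `tau`, `n_points`, `flag`.
#' @export
fit_growth <- function(tc) {
  stopifnot(all(c("time", "count", "mass") %in% names(tc)))
  if (all(tc$mass == 0)) stop("mass series is all zeros")
  div <- fit_division(tc)
  ok <- is.finite(tc$count) & tc$count > 0 & is.finite(tc$mass) & tc$mass > 0
  sub <- tc[ok, , drop = FALSE]
  if (length(unique(sub$time)) < 3)
    stop("need positive mass and counts at >= 3 timepoints")
  m <- sub$mass / sub$count
  fit <- lm(log(m) ~ time, data = data.frame(m = m, time = sub$time))
  gamma <- unname(coef(fit)["time"]) + div$alpha
  c(list(gamma = gamma), div)
}

#' Fit the full growth/division model of a condition
#'
#' Convenience wrapper returning a classed estimate combining
#' [fit_division()] and [fit_growth()].
#'
#' @param tc data.frame with columns `time`, `count`, `mass`.
#' @return Object of class `growth_fit`: `alpha`, `tau`, `gamma`,
#'   `n_points`, `flag`.
#' @export
fit_growth_model <- function(tc) {
  est <- fit_growth(tc)
  structure(est, class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("Exponential growth fit:\n")
  cat(sprintf("  division rate alpha = %.4f /h  (cycle length tau = %s h)\n",
              x$alpha, if (is.na(x$tau)) "NA" else sprintf("%.2f", x$tau)))
  cat(sprintf("  growth rate  gamma = %.4f /h\n", x$gamma))
  if (x$flag != "ok") cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' Normalize growth/division rates to an untreated control
#'
#' Computes control-normalized rates and the growth/division imbalance
#' `log2(gamma_tilde / alpha_tilde)`. Conditions on the proportionality
#' line (equal fold-changes of growth and division) have imbalance 0;
#' negative values tag growth-limited conditions (below the diagonal),
#' positive values division-limited ones.
#'
#' @param estimate,control `growth_fit` objects (or lists with `gamma`
#'   and `alpha`).
#' @return List with `gamma_norm`, `alpha_norm`, `imbalance`, and
#'   `limitation` (`"growth_limited"`, `"division_limited"` or
#'   `"balanced"`).
#' @export
normalize_to_control <- function(estimate, control) {
  if (!is.finite(control$gamma) || control$gamma <= 0 ||
      !is.finite(control$alpha) || control$alpha <= 0)
    stop("control rates must be positive")
  g <- estimate$gamma / control$gamma
  a <- estimate$alpha / control$alpha
  imb <- log2(g / a)
  list(gamma_norm = g, alpha_norm = a, imbalance = imb,
       limitation = if (imb < 0) "growth_limited"
                    else if (imb > 0) "division_limited" else "balanced")
}

#' Correlation between per-drug cell size and PC1
#'
#' Pearson correlation (with two-sided p-value) between condition-level
#' mean cell size and the drug's first-principal-component coordinate.
#'
#' @param per_drug_size Named numeric vector: drug -> mean cell size.
#' @param per_drug_pc1 Named numeric vector: drug -> PC1 coordinate.
#' @return List with `r`, `p_value`, `n`.
#' @export
size_state_correlation <- function(per_drug_size, per_drug_pc1) {
  common <- intersect(names(per_drug_size), names(per_drug_pc1))
  if (length(common) < 3) stop("need >= 3 drugs in common")
  ct <- cor.test(per_drug_size[common], per_drug_pc1[common],
                 method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(common))
}

#' Per-drug mean cell size from a screen cell table
#'
#' Median-of-cells summary (per drug, post-treatment timepoints only) of
#' the per-cell segmented area.
#'
#' @param cells Screen cell table with columns `drug`, `time`,
#'   `cell_area`.
#' @param time Timepoint to summarize (default: the latest).
#' @return Named numeric vector drug -> mean cell size.
#' @export
per_drug_cell_size <- function(cells, time = max(cells$time)) {
  sub <- cells[cells$time == time & cells$drug != "DMSO", , drop = FALSE]
  vapply(split(sub$cell_area, sub$drug), median, 0)
}
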