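#' Simulate a growth/division time course
#'
#' Bulk cell counts follow exponential proliferation,
#' `N(t) = N0 * 2^(t / cycle_length)`, and bulk protein mass follows
#' `M(t) = M0 * exp(growth_rate * t)` (per-cell mass synthesis at rate
#' `growth_rate` is conserved through divisions), so the mean per-cell
#' mass is `m(t) = m0 * exp((growth_rate - alpha) * t)` with
#' `alpha = log(2) / cycle_length`. Both series are multiplied by
#' mean-one lognormal noise of the requested coefficient of variation.
#'
#' @param growth_rate Per-cell mass accumulation rate (1/h, relative
#'   units).
#' @param cycle_length Cell-cycle length in hours (> 0).
#' @param times Measurement times in hours (nonempty).
#' @param replicates Number of independent replicate series (default 2,
#'   as in paired-replicate plate designs).
#' @param noise_cv Coefficient of variation of multiplicative lognormal
#'   noise; 0 gives exact trajectories.
#' @param seed Integer seed.
#' @param n0,m0 Initial cell count and initial mean per-cell mass.
#' @return data.frame of class `growth_timecourse` with columns
#'   `time`, `replicate`, `count`, `mass`.
#' @export
simulate_growth_timecourse <- function(growth_rate, cycle_length, times,
                                       replicates = 2, noise_cv = 0,
                                       seed = 1, n0 = 1000, m0 = 1) {
  stopifnot(cycle_length > 0, length(times) >= 1, replicates >= 1)
  if (noise_cv < 0) stop("'noise_cv' must be nonnegative")
  alpha <- log(2) / cycle_length
  tc <- expand.grid(time = sort(times), replicate = seq_len(replicates),
                    KEEP.OUT.ATTRS = FALSE)
  count <- n0 * 2^(tc$time / cycle_length)
  mass <- count * m0 * exp((growth_rate - alpha) * tc$time)
  if (noise_cv > 0) {
    tc_noise <- with_seed(seed, {
      sdl <- sqrt(log(1 + noise_cv^2))
      list(c = rlnorm(nrow(tc), -sdl^2 / 2, sdl),
           m = rlnorm(nrow(tc), -sdl^2 / 2, sdl))
    })
    count <- count * tc_noise$c
    mass <- mass * tc_noise$m
  }
  out <- data.frame(time = tc$time, replicate = tc$replicate,
                    count = count, mass = mass)
  class(out) <- c("growth_timecourse", "data.frame")
  out
}

#' Simulate cohort sample-by-protein matrices from a reference correlation
#'
#' Each cohort is drawn from a zero-mean, unit-variance multivariate
#' normal whose correlation matrix equals `reference_corr`, emulating
#' per-cancer protein panels whose correlation structure is to be compared
#' back to the reference.
#'
#' @param reference_corr Symmetric positive-semidefinite correlation
#'   matrix with unit diagonal; row/column names name the proteins.
#' @param n_samples Samples per cohort (scalar or one per cohort).
#' @param n_cohorts Number of cohorts.
#' @param seed Integer seed.
#' @return List of `n_cohorts` numeric sample-by-protein matrices; each
#'   has attributes `cohort` and `n_samples`.
#' @export
simulate_cohort_proteomes <- function(reference_corr, n_samples,
                                      n_cohorts = 1, seed = 1) {
  reference_corr <- as.matrix(reference_corr)
  p <- nrow(reference_corr)
  if (ncol(reference_corr) != p ||
      max(abs(reference_corr - t(reference_corr))) > 1e-8)
    stop("'reference_corr' must be symmetric")
  if (max(abs(diag(reference_corr) - 1)) > 1e-8)
    stop("'reference_corr' must have unit diagonal")
  ev <- eigen(reference_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop(sprintf("'reference_corr' is not positive semidefinite (eigenvalue %.3g)",
                 min(ev)))
  if (is.null(rownames(reference_corr)))
    rownames(reference_corr) <- colnames(reference_corr) <-
      paste0("P", seq_len(p))
  n_samples <- rep(n_samples, length.out = n_cohorts)
  seeds <- child_seeds(seed, paste0("cohort", seq_len(n_cohorts)))
  lapply(seq_len(n_cohorts), function(i) {
    x <- with_seed(seeds[i],
      MASS::mvrnorm(n_samples[i], mu = rep(0, p), Sigma = reference_corr))
    colnames(x) <- rownames(reference_corr)
    attr(x, "cohort") <- paste0("cohort_", i)
    attr(x, "n_samples") <- n_samples[i]
    x
  })
}
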