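#' Default reporter panel of the simulated screen
#'
#' Twelve signaling reporters: five kinase translocation reporters (KTR;
#' readout is the per-cell cytoplasm/nucleus intensity ratio) and seven
#' transcription-response-element reporters (TRE; readout is the
#' background-subtracted mean nuclear intensity).
#'
#' @return data.frame with columns `pathway` and `mode`
#'   (`"ratio"` or `"nuclear_intensity"`).
#' @export
default_pathways <- function() {
  data.frame(
    pathway = c("ERK", "p38", "JNK", "PKA", "AKT",
                "WNT", "p53", "NFkB", "RAR", "HIF", "YAPTAZ", "Geminin"),
    mode = c(rep("ratio", 5), rep("nuclear_intensity", 7)),
    stringsAsFactors = FALSE)
}

#' Design of a simulated pooled reporter screen
#'
#' Encodes the study conditions the generator emulates: 12 reporter clones
#' pooled in every well; drugs acting through a shared latent state axis
#' `u` (two anticorrelated pathway clusters: the five kinase reporters
#' versus six stress/transcription reporters, with the cell-cycle reporter
#' off-axis) plus drug-specific idiosyncratic effects; DMSO control wells
#' with well-to-well jitter; a saturating ramp of effect size over 0-48 h;
#' and per-well cell counts. Drug effect vectors are
#' `w_d(t) = ramp(t) * (s_d * u + e_d)` in units of the latent per-cell
#' readout SD.
#'
#' @param pathways data.frame as [default_pathways()].
#' @param n_pos,n_neg,n_idio Number of drugs loading positively on the
#'   state axis (growth-limiting, "p38-state"), negatively ("p53-state"),
#'   and off-axis (idiosyncratic only).
#' @param effect_range Range of |s_d| for state-axis drugs (latent SD units).
#' @param idio_sd Per-pathway SD of the idiosyncratic component `e_d` for
#'   state-axis drugs.
#' @param idio_norm_range Norm range of `e_d` for off-axis drugs.
#' @param n_dmso_wells Number of DMSO control wells.
#' @param wells_per_drug Replicate wells per drug.
#' @param timepoints Hours; must include 0 for pre-treatment baselines.
#' @param cells_per_well Expected cells per clone per well (Poisson mean).
#' @param tau_ramp Time constant (h) of the shared-state effect onset
#'   `(1 - exp(-t / tau_ramp))^2`.
#' @param tau_direct Time constant (h) of the fast saturating ramp
#'   `1 - exp(-t / tau_direct)` of the drug-specific direct component.
#' @param well_jitter_sd SD of the scalar well-level nuisance shift.
#' @param state_jitter_sd SD of the well-level shift along the state axis
#'   (pre-existing state variation present already at t = 0).
#' @param state_decay Time constant (h) with which a perturbation
#'   overrides the spontaneous well-state component in treated wells
#'   (`exp(-t / state_decay)`); control wells keep their state. This
#'   models the rapid elimination of pre-existing correlated activity in
#'   the first hour of treatment, before the drug-driven states emerge.
#' @param seed Integer master seed.
#' @return Object of class `screen_design`.
#' @export
screen_design <- function(pathways = default_pathways(),
                          n_pos = 40, n_neg = 40, n_idio = 20,
                          effect_range = c(1, 3), idio_sd = 0.15,
                          idio_norm_range = c(1, 2),
                          n_dmso_wells = 39, wells_per_drug = 3,
                          timepoints = c(0, 12, 24, 36, 48),
                          cells_per_well = 200,
                          tau_ramp = 12, tau_direct = 2,
                          well_jitter_sd = 0.05,
                          state_jitter_sd = 0.10, state_decay = 0.5,
                          seed = 1) {
  stopifnot(cells_per_well > 0, tau_ramp > 0, all(timepoints >= 0),
            n_dmso_wells >= 1, wells_per_drug >= 1)
  p <- nrow(pathways)
  u <- numeric(p)
  u[pathways$mode == "ratio"] <- 1
  u[pathways$pathway %in% c("WNT", "p53", "NFkB", "RAR", "HIF", "YAPTAZ")] <- -1
  if (all(u == 0)) u <- rep(1, p)  # non-default panels: uniform axis
  u <- u / sqrt(sum(u^2))
  names(u) <- pathways$pathway
  structure(list(pathways = pathways, u = u,
                 n_pos = n_pos, n_neg = n_neg, n_idio = n_idio,
                 effect_range = effect_range, idio_sd = idio_sd,
                 idio_norm_range = idio_norm_range,
                 n_dmso_wells = n_dmso_wells,
                 wells_per_drug = wells_per_drug,
                 timepoints = sort(unique(timepoints)),
                 cells_per_well = cells_per_well,
                 tau_ramp = tau_ramp, tau_direct = tau_direct,
                 well_jitter_sd = well_jitter_sd,
                 state_jitter_sd = state_jitter_sd,
                 state_decay = state_decay,
                 seed = seed),
            class = "screen_design")
}

#' @export
print.screen_design <- function(x, ...) {
  cat("Simulated screen design:", x$n_pos + x$n_neg + x$n_idio, "drugs (",
      x$n_pos, "+axis,", x$n_neg, "-axis,", x$n_idio, "off-axis ),",
      nrow(x$pathways), "reporters,", x$n_dmso_wells, "DMSO wells,",
      length(x$timepoints), "timepoints\n")
  invisible(x)
}

# Direct (drug-specific) effects rise as a plain saturating exponential;
# the shared-state component has a sigmoidal onset (squared saturating
# exponential): direct target engagement is fast, while the generalized
# state response is absent in the first hour and gains prominence
# progressively over the 48 h time course.
ramp_fun <- function(t, tau) 1 - exp(-t / tau)
ramp_state_fun <- function(t, tau) (1 - exp(-t / tau))^2

#' Simulate a pooled reporter screen
#'
#' Draws one row per simulated cell. Latent per-cell activity is normal
#' with unit SD; a drug shifts its location by `w_d(t)[pathway]`, wells
#' contribute a scalar nuisance shift plus a persistent shift along the
#' state axis, and DMSO wells have `w = 0`. KTR readouts are a logistic
#' transform of the latent activity mapped onto a positive
#' cytoplasm/nucleus ratio scale; TRE readouts are lognormal nuclear
#' intensities. Per-condition cell counts are Poisson. A per-cell area is
#' drawn around the drug's true mean cell size, which is coupled to the
#' latent state (state-axis-positive drugs shrink cells, negative enlarge
#' them) together with true growth/division rates.
#'
#' @param design A [screen_design()].
#' @return A list with `cells` (data.frame: well, drug, time, clone,
#'   pathway, mode, readout_ratio, readout_nuclear, cell_area) and
#'   `truth` (list: `u`, `drugs` with `s` and per-drug rates/sizes,
#'   `effects` the drug x pathway x time array `w_d(t)`, well effects).
#' @export
simulate_screen <- function(design) {
  stopifnot(inherits(design, "screen_design"))
  d <- design
  p <- nrow(d$pathways)
  seeds <- child_seeds(d$seed, c("drugs", "wells", "cells"))
  n_drugs <- d$n_pos + d$n_neg + d$n_idio
  drug_ids <- sprintf("D%03d", seq_len(n_drugs))
  group <- rep(c("pos", "neg", "idio"), c(d$n_pos, d$n_neg, d$n_idio))

  truth <- with_seed(seeds["drugs"], {
    s <- numeric(n_drugs)
    s[group == "pos"] <- runif(d$n_pos, d$effect_range[1], d$effect_range[2])
    s[group == "neg"] <- -runif(d$n_neg, d$effect_range[1], d$effect_range[2])
    e <- matrix(0, n_drugs, p)
    on_axis <- group != "idio"
    e[on_axis, ] <- rnorm(sum(on_axis) * p, sd = d$idio_sd)
    if (any(!on_axis)) {
      for (i in which(!on_axis)) {
        v <- rnorm(p)
        v <- v - sum(v * d$u) * d$u          # off-axis: orthogonal to u
        v <- v / sqrt(sum(v^2))
        e[i, ] <- v * runif(1, d$idio_norm_range[1], d$idio_norm_range[2])
      }
    }
    # Growth/division coupling: positive state = growth-limited (smaller
    # cells), negative state = division-limited (larger cells).
    gamma0 <- log(2) / 20  # control mass accumulation rate, 1/h
    alpha0 <- log(2) / 22  # control division rate, 1/h
    sp <- pmax(s, 0); sn <- pmax(-s, 0)
    gamma_d <- gamma0 * 2^(-0.30 * sp - 0.05 * sn)
    alpha_d <- alpha0 * 2^(-0.10 * sp - 0.35 * sn)
    size_d <- 650 * (gamma_d / alpha_d) / (gamma0 / alpha0)
    list(s = s, e = e, gamma = gamma_d, alpha = alpha_d, size = size_d,
         gamma0 = gamma0, alpha0 = alpha0)
  })

  # effect array w_d(t) = ramp_state(t) s_d u + ramp_direct(t) e_d
  state_eff <- truth$s %o% d$u
  ramp <- ramp_state_fun(d$timepoints, d$tau_ramp)
  ramp_dir <- ramp_fun(d$timepoints, d$tau_direct)
  effects <- array(0, dim = c(n_drugs, p, length(d$timepoints)),
                   dimnames = list(drug_ids, d$pathways$pathway,
                                   paste0("t", d$timepoints)))
  for (k in seq_along(ramp))
    effects[, , k] <- state_eff * ramp[k] + truth$e * ramp_dir[k]

  wells <- data.frame(
    well = c(sprintf("DMSO_%02d", seq_len(d$n_dmso_wells)),
             paste0(rep(drug_ids, each = d$wells_per_drug), "_w",
                    rep(seq_len(d$wells_per_drug), n_drugs))),
    drug = c(rep("DMSO", d$n_dmso_wells),
             rep(drug_ids, each = d$wells_per_drug)),
    stringsAsFactors = FALSE)
  wells <- with_seed(seeds["wells"], {
    wells$jitter <- rnorm(nrow(wells), sd = d$well_jitter_sd)
    wells$state_jitter <- rnorm(nrow(wells), sd = d$state_jitter_sd)
    wells
  })

  cells <- with_seed(seeds["cells"], {
    grid <- expand.grid(well_i = seq_len(nrow(wells)),
                        path_i = seq_len(p),
                        time_i = seq_along(d$timepoints),
                        KEEP.OUT.ATTRS = FALSE)
    n_cells <- rpois(nrow(grid), d$cells_per_well)
    gi <- rep(seq_len(nrow(grid)), n_cells)
    wi <- grid$well_i[gi]; pi_ <- grid$path_i[gi]; ti <- grid$time_i[gi]
    drug <- wells$drug[wi]
    di <- match(drug, drug_ids)            # NA for DMSO
    state_keep <- ifelse(is.na(di), 1,
                         exp(-d$timepoints[ti] / d$state_decay))
    shift <- ifelse(is.na(di), 0, effects[cbind(di, pi_, ti)]) +
      wells$jitter[wi] + wells$state_jitter[wi] * d$u[pi_] * state_keep
    z <- rnorm(length(gi), mean = shift, sd = 1)
    mode <- d$pathways$mode[pi_]
    ratio <- ifelse(mode == "ratio", 0.2 + 3.8 * stats::plogis(z), NA_real_)
    nuc <- ifelse(mode == "nuclear_intensity", 100 * exp(0.4 * z), NA_real_)
    size_mu <- ifelse(is.na(di), 650,
                      650 + (truth$size[ifelse(is.na(di), 1L, di)] - 650) *
                        ramp[ti])
    area <- rlnorm(length(gi), log(size_mu) - 0.5 * 0.3^2, 0.3)
    data.frame(well = wells$well[wi], drug = drug,
               time = d$timepoints[ti],
               clone = d$pathways$pathway[pi_],
               pathway = d$pathways$pathway[pi_],
               mode = mode,
               readout_ratio = ratio, readout_nuclear = nuc,
               cell_area = area, stringsAsFactors = FALSE)
  })

  list(cells = cells,
       truth = list(u = d$u,
                    drugs = data.frame(drug = drug_ids, group = group,
                                       s = truth$s,
                                       gamma = truth$gamma,
                                       alpha = truth$alpha,
                                       size = truth$size,
                                       stringsAsFactors = FALSE),
                    e = truth$e, effects = effects, wells = wells,
                    gamma0 = truth$gamma0, alpha0 = truth$alpha0),
       design = d)
}
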