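#' Parameters of the synthetic batch-culture world
#'
#' Defaults describe the degradation scenario the analysis modules were built
#' for: an inoculum of 5.7e5 cells mL^-1 growing exponentially at 0.09 h^-1
#' to a peak at 32 h on a 44 umol L^-1 dissolved-organic-carbon amendment
#' (above a 70 umol L^-1 coastal background), coupled to DOC drawdown through
#' a growth efficiency of 0.65 at 19.8 fg C cell^-1; an 11 umol L^-1
#' amino-acid amendment that is 55% free amino acids, consumed first-order
#' (DFAA first, then DCAA once < 3% of the DFAA pool remains); linear
#' ammonium (0.29 umol L^-1 h^-1) and phosphate (0.016 umol L^-1 h^-1)
#' accumulation from remineralisation; a transient leucine bump and a late
#' linear tryptophan rise; and 5% multiplicative lognormal measurement noise.
#'
#' @param seed Integer seed; every generator is deterministic given it.
#' @param mu_per_h Exponential growth rate of the amended community, h^-1.
#' @param mu_control_per_h Growth rate in unamended controls, h^-1.
#' @param n0_cells_per_mL Inoculum abundance after dilution into the flask.
#' @param bge Growth efficiency coupling DOC drawdown to biomass, in (0, 1.5].
#' @param bge_control Growth efficiency of the control community.
#' @param fg_c_per_cell Per-cell carbon, fg.
#' @param doc_amendment_umol_L DOC pulse above background.
#' @param doc_background_umol_L Ambient DOC.
#' @param thdaa_amendment_umol_L Hydrolyzable amino-acid pulse above background.
#' @param thdaa_background_umol_L Ambient TDHAA (88% of it combined).
#' @param dfaa_fraction Free fraction of the amino-acid amendment, in [0, 1].
#' @param k_dfaa_per_h,k_dcaa_per_h First-order consumption rates of the free
#'   and (after the switch) combined amino-acid pools.
#' @param nh4_0_umol_L,nh4_slope_umol_L_h Ammonium start and accumulation.
#' @param po4_0_umol_L,po4_slope_umol_L_h Phosphate start and accumulation.
#' @param no3no2_umol_L Constant nitrate + nitrite background.
#' @param don_slope_umol_L_h Net organic-nitrogen accumulation rate.
#' @param leucine_peak_umol_L Height of the transient leucine bump (at the
#'   abundance peak).
#' @param trp_slope_umol_L_h Tryptophan accumulation rate after the
#'   stationary phase starts (46 h).
#' @param peak_time_h Abundance-peak time.
#' @param decay_rate_per_h Exponential cell decay after the peak.
#' @param leach_k_per_h First-order leaching constant (plateau by ~24 h).
#' @param noise_cv Default coefficient of variation of the multiplicative
#'   lognormal measurement noise; per-analyte overrides via `noise_cv_by`.
#' @param noise_cv_by Named list/vector of per-analyte noise CVs.
#' @param n_replicates Flasks per treatment arm.
#' @param grid_exp1,grid_exp2 Sampling grids (h) of the two experiments.
#' @param mag_profile Named proportions of the community's genomes (sums
#'   to 1).
#' @return A `sim_params` list.
#' @export
sim_params <- function(seed = 1L,
                       mu_per_h = 0.09,
                       mu_control_per_h = 0.02,
                       n0_cells_per_mL = 5.7e5,
                       bge = 0.65,
                       bge_control = 0.05,
                       fg_c_per_cell = default_fg_c_per_cell,
                       doc_amendment_umol_L = 44,
                       doc_background_umol_L = 70,
                       thdaa_amendment_umol_L = 11,
                       thdaa_background_umol_L = 1,
                       dfaa_fraction = 0.55,
                       k_dfaa_per_h = 0.08,
                       k_dcaa_per_h = 0.05,
                       nh4_0_umol_L = 0.5,
                       nh4_slope_umol_L_h = 0.29,
                       po4_0_umol_L = 0.1,
                       po4_slope_umol_L_h = 0.016,
                       no3no2_umol_L = 0.35,
                       don_slope_umol_L_h = 0.26,
                       leucine_peak_umol_L = 3.9,
                       trp_slope_umol_L_h = 0.0038,
                       peak_time_h = 32,
                       decay_rate_per_h = 0.04,
                       leach_k_per_h = 0.15,
                       noise_cv = 0.05,
                       noise_cv_by = list(),
                       n_replicates = 3L,
                       grid_exp1 = c(0, 6, 12, 24, 32),
                       grid_exp2 = c(0, 12, 32, 46, 56, 80, 84),
                       mag_profile = c(Alteromonas = 0.43,
                                       Pseudoalteromonas = 0.39,
                                       Vibrio = 0.07, Others = 0.11)) {
  stopifnot(mu_per_h >= 0, n0_cells_per_mL > 0,
            bge > 0, bge <= 1.5, bge_control > 0,
            dfaa_fraction >= 0, dfaa_fraction <= 1,
            k_dfaa_per_h >= 0, k_dcaa_per_h >= 0,
            noise_cv >= 0, n_replicates >= 1L,
            abs(sum(mag_profile) - 1) < 1e-9)
  p <- as.list(environment())
  class(p) <- "sim_params"
  p
}

## mean-one multiplicative lognormal noise
ln_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

noise_cv_for <- function(params, analyte) {
  cv <- params$noise_cv_by[[analyte]]
  if (is.null(cv)) params$noise_cv else cv
}

#' Simulate a leaching experiment
#'
#' Each analyte follows first-order leaching to a plateau,
#' `C(t) = C_plateau (1 - exp(-k t))`, sampled at 0, 0.5, 1, 2, 6, 8, 12 and
#' 24 h in duplicate flasks with duplicate technical measurements, under
#' multiplicative lognormal noise. Default plateaus are chosen so the 24-h
#' endpoint estimator reproduces release rates of the magnitude the package's
#' worked example uses (plateau = rate x dm_mass / volume).
#'
#' @param params A [sim_params()] (uses `seed`, `leach_k_per_h`, `noise_cv`).
#' @param analyte_targets Named release rates (umol mg^-1 d^-1) defining the
#'   plateaus.
#' @param setup A [leaching_setup()].
#' @param grid_h Sampling grid, hours.
#' @param n_flasks,n_tech Flask and technical replication.
#' @return Tidy series ([ts_record()]) with attribute `"ground_truth"`.
#' @export
simulate_leaching <- function(params = sim_params(),
                              analyte_targets = c(POC = 0.42, PN = 0.12,
                                                  DOC = 0.44, TDN = 0.13,
                                                  NH4 = 0.0069, NO3 = 0.0034,
                                                  NO2 = 0.00058, PO4 = 0.0063,
                                                  THDAA = 0.109),
                              setup = leaching_setup(),
                              grid_h = c(0, 0.5, 1, 2, 6, 8, 12, 24),
                              n_flasks = 2L, n_tech = 2L) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  k <- params$leach_k_per_h
  plateaus <- analyte_targets * setup$dm_mass_mg / setup$volume_L
  rows <- list()
  for (an in names(analyte_targets)) {
    cv <- noise_cv_for(params, an)
    truth <- plateaus[[an]] * (1 - exp(-k * grid_h))
    for (f in seq_len(n_flasks)) {
      for (tech in seq_len(n_tech)) {
        rows[[length(rows) + 1L]] <- ts_record(
          grid_h, truth * ln_noise(length(grid_h), cv), analyte = an,
          unit = "umol/L", replicate = paste0("F", f),
          treatment = "leaching", experiment = "leach"
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "ground_truth") <- list(k_per_h = k, plateaus_umol_L = plateaus,
                                    rates_umol_mg_d = analyte_targets)
  out
}

## cell trajectory: exponential to the peak, exponential decay after
sim_cells <- function(t, n0, mu, peak, decay) {
  n_peak <- n0 * exp(mu * peak)
  ifelse(t <= peak, n0 * exp(mu * t), n_peak * exp(-decay * (t - peak)))
}

#' Simulate a batch-culture degradation experiment
#'
#' Generates tidy multi-analyte time series for amended ("jelly") and
#' unamended ("control") flasks on one experiment's sampling grid. The carbon
#' coupling is the budget identity itself: at zero noise
#' `DOC(t) = DOC0 - (N(t) - N0) * fg_c * 1e-9 / (bge * 12.011)` (umol C
#' L^-1, cells per litre), so every downstream estimator recovers the
#' programmed growth rate and growth efficiency exactly -- the closure the
#' recovery tests rely on. Amino-acid, nutrient, leucine and tryptophan
#' dynamics follow the shapes described in [sim_params()].
#'
#' @param params A [sim_params()].
#' @param experiment `"I"` (grid `grid_exp1`) or `"II"` (grid `grid_exp2`).
#' @param treatments Which arms to generate.
#' @return Tidy series with attribute `"ground_truth"` (the parameter list).
#' @export
simulate_batch_culture <- function(params = sim_params(),
                                   experiment = c("I", "II"),
                                   treatments = c("jelly", "control")) {
  stopifnot(inherits(params, "sim_params"))
  experiment <- match.arg(experiment)
  if (params$bge <= 0) stop("bge must be > 0", call. = FALSE)
  set.seed(params$seed + ifelse(experiment == "I", 0L, 1L))
  grid <- if (experiment == "I") params$grid_exp1 else params$grid_exp2
  peak <- params$peak_time_h
  fgc <- params$fg_c_per_cell
  t_switch <- if (params$k_dfaa_per_h > 0) {
    log(1 / 0.03) / params$k_dfaa_per_h         # DFAA down to 3% -> DCAA starts
  } else Inf

  jelly_truth <- function(t) {
    cells <- sim_cells(t, params$n0_cells_per_mL, params$mu_per_h, peak,
                       params$decay_rate_per_h)
    grown <- pmin(t, peak)
    n_l <- sim_cells(grown, params$n0_cells_per_mL, params$mu_per_h, peak,
                     params$decay_rate_per_h) * 1000
    drawdown <- (n_l - params$n0_cells_per_mL * 1000) * fgc * 1e-9 /
      (params$bge * atomic_masses[["C"]])
    doc <- params$doc_background_umol_L + params$doc_amendment_umol_L - drawdown
    dfaa0 <- params$dfaa_fraction * params$thdaa_amendment_umol_L +
      0.12 * params$thdaa_background_umol_L
    dcaa0 <- (1 - params$dfaa_fraction) * params$thdaa_amendment_umol_L +
      0.88 * params$thdaa_background_umol_L
    dfaa <- dfaa0 * exp(-params$k_dfaa_per_h * t)
    dcaa <- ifelse(t <= t_switch, dcaa0,
                   dcaa0 * exp(-params$k_dcaa_per_h * (t - t_switch)))
    nh4 <- params$nh4_0_umol_L + params$nh4_slope_umol_L_h * t
    po4 <- params$po4_0_umol_L + params$po4_slope_umol_L_h * t
    don0 <- 13 - params$nh4_0_umol_L - params$no3no2_umol_L
    don <- don0 + params$don_slope_umol_L_h * t
    leu <- params$leucine_peak_umol_L * (t / peak) * exp(1 - t / peak)
    trp <- ifelse(t > 46, params$trp_slope_umol_L_h * (t - 46), 0)
    list(cells = cells, DOC = doc, DFAA = dfaa, DCAA = dcaa,
         TDHAA = dfaa + dcaa, NH4 = nh4, PO4 = po4, DON = don,
         TDN = don + nh4 + params$no3no2_umol_L,
         leucine = leu, tryptophan = trp)
  }
  control_truth <- function(t) {
    cells <- params$n0_cells_per_mL * exp(params$mu_control_per_h * pmin(t, peak))
    n_l <- cells * 1000
    drawdown <- (n_l - params$n0_cells_per_mL * 1000) * fgc * 1e-9 /
      (params$bge_control * atomic_masses[["C"]])
    doc <- params$doc_background_umol_L - drawdown
    dfaa <- rep(0.12 * params$thdaa_background_umol_L, length(t))
    dcaa <- rep(0.88 * params$thdaa_background_umol_L, length(t))
    nh4 <- rep(params$nh4_0_umol_L, length(t))
    po4 <- rep(params$po4_0_umol_L, length(t))
    don <- rep(2, length(t))
    list(cells = cells, DOC = doc, DFAA = dfaa, DCAA = dcaa,
         TDHAA = dfaa + dcaa, NH4 = nh4, PO4 = po4, DON = don,
         TDN = don + nh4 + params$no3no2_umol_L,
         leucine = rep(0, length(t)), tryptophan = rep(0, length(t)))
  }

  rows <- list()
  for (arm in treatments) {
    truth <- if (arm == "jelly") jelly_truth(grid) else control_truth(grid)
    for (r in seq_len(params$n_replicates)) {
      for (an in names(truth)) {
        cv <- noise_cv_for(params, an)
        unit <- if (an == "cells") "cells/mL" else "umol/L"
        rows[[length(rows) + 1L]] <- ts_record(
          grid, truth[[an]] * ln_noise(length(grid), cv), analyte = an,
          unit = unit,
          replicate = paste0(toupper(substr(arm, 1, 1)), r),
          treatment = arm, experiment = experiment
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  truth_params <- unclass(params)
  truth_params$noise_cv_by <- NULL
  attr(out, "ground_truth") <- truth_params
  out
}

#' Default synthetic protein table
#'
#' Ten proteins covering the annotation spectrum of a gelatinous-zooplankton
#' detritus proteome. Initial weights (`weight0`, fractions of the t = 0
#' PSMs/AA pool) and two decay-rate classes: a fast-degrading bulk (98% of
#' the pool at 0.1185 h^-1) and degradation-resistant actin-/titin-like
#' proteins (2% at 0.0419 h^-1). The two rates were solved analytically so
#' that a 203.45 PSMs/AA pool declines to 5.56 at 32 h and 0.13 at 84 h.
#'
#' @return Data frame with `protein_id`, `annotation`, `aa_length`,
#'   `weight0`, `decay_per_h`.
#' @export
default_protein_table <- function() {
  fast <- 0.1185; slow <- 0.0419
  data.frame(
    protein_id = c("P01", "P02", "P03", "P04", "P05", "P06", "P07", "P08",
                   "P09", "P10"),
    annotation = c("fibrillin-like", "myosin-like", "ubiquitin-like",
                   "ribosomal", "collagen alpha chain-like",
                   "non-ribosomal peptide synthetase", "serine protease",
                   "uncharacterized", "actin-like", "titin-like"),
    aa_length = c(2871, 1938, 76, 250, 1400, 4500, 410, 350, 375, 34350),
    weight0 = c(0.08, 0.07, 0.03, 0.03, 0.01, 0.02, 0.01, 0.73, 0.015, 0.005),
    decay_per_h = c(rep(fast, 8), slow, slow),
    stringsAsFactors = FALSE
  )
}

#' Simulate a PSM table with per-protein exponential decay
#'
#' Each protein's PSMs/AA decays at its own first-order rate; the table is
#' scaled so the t = 0 pool total equals `pool0`. Optional Poisson noise is
#' applied to the PSM counts (which are otherwise continuous).
#'
#' @param params A [sim_params()] (used for the seed).
#' @param proteins Protein table as [default_protein_table()] (`weight0`
#'   normalised internally).
#' @param timepoints_h Sampling times, hours.
#' @param pool0 Target t = 0 pool total (PSMs/AA).
#' @param noise `"none"` (default) or `"poisson"`.
#' @return PSM records: `protein_id`, `annotation`, `aa_length`, `psms`,
#'   `timepoint_h`, with attribute `"ground_truth"`.
#' @export
simulate_psm_table <- function(params = sim_params(),
                               proteins = default_protein_table(),
                               timepoints_h = c(0, 32, 84),
                               pool0 = 203.45,
                               noise = c("none", "poisson")) {
  noise <- match.arg(noise)
  stopifnot(nrow(proteins) >= 1L, all(proteins$decay_per_h >= 0))
  set.seed(params$seed)
  w <- proteins$weight0 / sum(proteins$weight0)
  rows <- lapply(timepoints_h, function(tp) {
    ppa <- w * pool0 * exp(-proteins$decay_per_h * tp)
    psms <- ppa * proteins$aa_length
    if (noise == "poisson") psms <- rpois(length(psms), psms)
    data.frame(protein_id = proteins$protein_id,
               annotation = proteins$annotation,
               aa_length = proteins$aa_length,
               psms = psms, timepoint_h = tp, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "ground_truth") <- list(pool0 = pool0,
                                    decay_per_h = setNames(proteins$decay_per_h,
                                                           proteins$protein_id))
  out
}

#' Simulate mapped-read counts over genomes of unequal length
#'
#' Draws one multinomial read vector with probabilities proportional to
#' `proportion x length` -- the sampling model under which length-normalised
#' RPM recovers the programmed community profile in expectation.
#'
#' @param mag_profile Named proportions summing to 1.
#' @param total_reads Total mapped reads (> 0).
#' @param lengths Genome lengths in bp (default 3 Mbp each).
#' @param seed Integer seed.
#' @param sample_id Sample identifier.
#' @return FeatureCount data frame (`sample_id`, `feature_id`, `length`,
#'   `mapped_reads`).
#' @export
simulate_read_counts <- function(mag_profile, total_reads = 1e6,
                                 lengths = NULL, seed = 1L,
                                 sample_id = "sample1") {
  stopifnot(abs(sum(mag_profile) - 1) < 1e-9, all(mag_profile >= 0))
  if (total_reads <= 0) stop("total_reads must be > 0", call. = FALSE)
  if (is.null(lengths)) lengths <- rep(3e6, length(mag_profile))
  stopifnot(length(lengths) == length(mag_profile), all(lengths > 0))
  set.seed(seed)
  prob <- mag_profile * lengths
  reads <- as.vector(rmultinom(1, size = total_reads, prob = prob))
  data.frame(sample_id = sample_id, feature_id = names(mag_profile),
             length = lengths, mapped_reads = reads,
             stringsAsFactors = FALSE)
}

#' Write a simulator's ground truth as JSON
#'
#' @param x A simulated table carrying a `"ground_truth"` attribute.
#' @param path Output JSON path.
#' @export
write_ground_truth <- function(x, path) {
  gt <- attr(x, "ground_truth")
  if (is.null(gt)) stop("no ground_truth attribute on this object", call. = FALSE)
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
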