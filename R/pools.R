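#' Dissolved combined amino acids by difference
#'
#' DCAA = TDHAA - DFAA at a common timepoint and unit. Measurement noise can
#' drive the difference negative; negative results are returned with a
#' warning, not clamped.
#'
#' @param thdaa Total dissolved hydrolyzable amino acids.
#' @param dfaa Dissolved free amino acids (same unit).
#' @param unit_thdaa,unit_dfaa Optional unit strings; a mismatch is an error.
#' @return DCAA concentration (vectorised).
#' @export
dcaa <- function(thdaa, dfaa, unit_thdaa = NULL, unit_dfaa = NULL) {
  if (!is.null(unit_thdaa) && !is.null(unit_dfaa) &&
      !identical(unit_thdaa, unit_dfaa)) {
    stop("unit mismatch: TDHAA in ", unit_thdaa, ", DFAA in ", unit_dfaa,
         call. = FALSE)
  }
  out <- thdaa - dfaa
  if (any(out < 0)) warning("negative DCAA (DFAA > TDHAA): measurement noise?")
  out
}

#' Canonical amino-acid species pooling
#'
#' Chromatographic amino-acid analysis cannot separate glutamate from
#' glutamine (reported as Glx) nor aspartate from asparagine (Asx). This map
#' is applied by [canonicalize_profile()]; edit or extend it to taste.
#'
#' @return Data frame with columns `species` and `canonical`.
#' @export
aa_canonical_map <- function() {
  data.frame(
    species   = c("Glu", "Gln", "Asp", "Asn"),
    canonical = c("Glx", "Glx", "Asx", "Asx"),
    stringsAsFactors = FALSE
  )
}

#' Pool synonymous species in an amino-acid profile
#'
#' @param profile Named numeric vector of species concentrations.
#' @param map A data frame like [aa_canonical_map()].
#' @return Named vector with pooled (Glx/Asx) species summed.
#' @export
canonicalize_profile <- function(profile, map = aa_canonical_map()) {
  nm <- names(profile)
  stopifnot(!is.null(nm))
  idx <- match(nm, map$species)
  nm[!is.na(idx)] <- map$canonical[idx[!is.na(idx)]]
  tapply_sum <- tapply(profile, nm, sum)
  out <- as.numeric(tapply_sum)
  names(out) <- names(tapply_sum)
  out
}

#' Mole-percent composition of an amino-acid profile
#'
#' Shares of each species in the molar total; sums to 100 within 1e-9.
#' Negative entries (e.g. negative DCAA from noise) are flagged and excluded
#' from the computation.
#'
#' @param profile Named numeric vector of molar concentrations.
#' @return Named numeric vector of mol% shares.
#' @export
mol_percent <- function(profile) {
  stopifnot(is.numeric(profile), length(profile) >= 1L)
  if (any(profile < 0)) {
    warning("negative species excluded from mol% computation")
    profile <- profile[profile >= 0]
  }
  total <- sum(profile)
  if (total <= 0) stop("profile has no positive total: mol% undefined",
                       call. = FALSE)
  100 * profile / total
}

#' Growth-phase windows of a batch culture
#'
#' Default boundaries: exponential from 0 h to the abundance peak, stationary
#' from the peak to 46 h, senescent from 46 h to the end. The boundaries are
#' configuration, not inference -- supply your own to match your experiment.
#'
#' @param peak_h Abundance-peak time, h (default 32).
#' @param stationary_end_h End of the stationary phase, h (default 46).
#' @param end_h Experiment end, h (default 84).
#' @return Named list of `c(t_start_h, t_end_h)` windows, non-overlapping and
#'   ordered.
#' @export
phase_windows <- function(peak_h = 32, stationary_end_h = 46, end_h = 84) {
  stopifnot(0 < peak_h, peak_h <= stationary_end_h, stationary_end_h <= end_h)
  list(exponential = c(0, peak_h),
       stationary = c(peak_h, stationary_end_h),
       senescent = c(stationary_end_h, end_h))
}

#' Signed net rate of an analyte over a growth phase
#'
#' Slope of concentration vs time within the phase window, per replicate,
#' then mean and SD across replicates. Sign convention: negative = net
#' consumption, positive = net accumulation. Rates whose magnitude falls
#' below `floor` are reported in the `display` field as `"<floor"`.
#'
#' @param series Tidy series ([ts_record()]) of one analyte; may hold several
#'   replicates.
#' @param phase `c(t_start_h, t_end_h)` or an entry of [phase_windows()].
#' @param method `"ols"` (default) or `"endpoint"`.
#' @param label Phase label carried into the result.
#' @param floor Quantification floor in the series' unit per hour (default 0,
#'   i.e. off; use e.g. 1 nmol L^-1 h^-1 scaled to your unit).
#' @return A `net_rate` list: `analyte`, `phase`, `rate`, `sd`, `n`,
#'   `unit_per_h`, `display`.
#' @export
net_rate <- function(series, phase, method = c("ols", "endpoint"),
                     label = NA_character_, floor = 0) {
  method <- match.arg(method)
  validate_series(series)
  analyte <- unique(series$analyte)
  stopifnot(length(analyte) == 1L, length(phase) == 2L, phase[2] > phase[1])
  per_rep <- vapply(split(series, series$replicate), function(df) {
    sel <- df$time_h >= phase[1] - 1e-9 & df$time_h <= phase[2] + 1e-9
    df <- df[sel, ]
    if (nrow(df) < 2L) stop("fewer than 2 points in phase window for ",
                            analyte, call. = FALSE)
    slope_per_h(df$time_h, df$value, method)
  }, numeric(1))
  rate <- mean(per_rep)
  unit <- paste0(unique(series$unit), "/h")
  structure(list(
    analyte = analyte, phase = label, rate = rate,
    sd = if (length(per_rep) > 1L) sd(per_rep) else NA_real_,
    n = length(per_rep), unit_per_h = unit,
    display = if (abs(rate) < floor) paste0("<", floor) else
      formatC(rate, digits = 3, format = "g")
  ), class = "net_rate")
}

#' @export
print.net_rate <- function(x, ...) {
  cat(sprintf("%s net rate (%s): %s %s", x$analyte,
              ifelse(is.na(x$phase), "phase", x$phase), x$display, x$unit_per_h))
  if (!is.na(x$sd)) cat(sprintf(" (sd %.3g, n = %d)", x$sd, x$n))
  cat("\n")
  invisible(x)
}

#' Percentage of a pool still present
#'
#' `100 * current / initial`; the complement of [fraction_consumed()].
#'
#' @param initial_pool Initial pool (> 0).
#' @param current_pool Current pool (>= 0).
#' @return Percent of the initial pool remaining.
#' @export
pool_fraction_remaining <- function(initial_pool, current_pool) {
  if (any(initial_pool <= 0)) stop("initial pool must be > 0", call. = FALSE)
  100 * current_pool / initial_pool
}

#' Molar DOC:DON ratio at a timepoint
#'
#' @param doc,don Concentrations (umol L^-1) at the same timepoint; `don > 0`.
#' @return Dimensionless molar ratio.
#' @export
doc_don_ratio <- function(doc, don) {
  if (any(don == 0)) stop("DON is zero: DOC:DON undefined", call. = FALSE)
  doc / don
}
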