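#' Describe a leaching-experiment setup
#'
#' @param dm_mass_mg Jellyfish dry mass added to the flask, mg (> 0).
#' @param volume_L Flask volume, L (> 0). Default 250 mg in 1 L.
#' @param duration_h Experiment duration, h (> 0).
#' @param replicate_id Optional flask identifier.
#' @return A `leaching_setup` list.
#' @export
leaching_setup <- function(dm_mass_mg = 250, volume_L = 1, duration_h = 24,
                           replicate_id = NA_character_) {
  stopifnot(dm_mass_mg > 0, volume_L > 0, duration_h > 0)
  structure(list(dm_mass_mg = dm_mass_mg, volume_L = volume_L,
                 duration_h = duration_h, replicate_id = replicate_id),
            class = "leaching_setup")
}

#' Per-dry-mass release rate from a leaching time series
#'
#' Converts concentration time series (umol L^-1 vs hours) into release rates
#' in umol (mg dry mass)^-1 d^-1: `slope_per_hour * 24 * volume_L / dm_mass_mg`.
#' With `method = "ols"` the slope is the least-squares fit over the
#' pre-plateau segment (the contiguous prefix of >= 3 points maximising R^2,
#' so a saturating curve is fitted on its rising limb and perfectly linear
#' data use every point); `method = "endpoint"` uses the first and last
#' points only. Replicate flasks are fitted independently and averaged.
#'
#' Negative rates (consumption or adsorption artifacts) are reported with
#' sign and flagged, never clamped.
#'
#' @param series Tidy series ([ts_record()]) for a single analyte in umol/L
#'   (or nmol/L); may contain several `replicate` values.
#' @param setup A [leaching_setup()].
#' @param method `"ols"` (default) or `"endpoint"`.
#' @return A `release_rate` list: `analyte`, `rate` (umol mg^-1 d^-1), `sd`
#'   (across replicates; `NA` for a single flask), `n_replicates`, `method`,
#'   `replicate_rates`, and a `negative` flag.
#' @export
release_rate <- function(series, setup = leaching_setup(),
                         method = c("ols", "endpoint")) {
  method <- match.arg(method)
  validate_series(series)
  stopifnot(inherits(setup, "leaching_setup"))
  analyte <- unique(series$analyte)
  if (length(analyte) != 1L) {
    stop("release_rate() expects a single analyte, got: ",
         paste(analyte, collapse = ", "), call. = FALSE)
  }
  per_rep <- vapply(split(series, series$replicate), function(rep_df) {
    ## average duplicate technical measurements at identical times first
    yt <- tapply(rep_df$value, rep_df$time_h, mean)
    tt <- as.numeric(names(yt)); yy <- as.numeric(yt)
    if (length(tt) < 2L) {
      stop("release_rate() needs >= 2 timepoints per replicate", call. = FALSE)
    }
    sl <- if (method == "ols") {
      idx <- best_prefix(tt, yy)
      ols_fit(tt[idx], yy[idx])$slope
    } else {
      endpoint_slope(tt, yy)
    }
    sl * 24 * setup$volume_L / setup$dm_mass_mg
  }, numeric(1))
  rate <- mean(per_rep)
  structure(list(
    analyte = analyte, rate = rate,
    sd = if (length(per_rep) > 1L) sd(per_rep) else NA_real_,
    n_replicates = length(per_rep), method = method,
    replicate_rates = per_rep, negative = rate < 0
  ), class = "release_rate")
}

## construct a release_rate from bare numbers (printed tables are inputs too)
#' Release rate from a printed value
#'
#' Wraps an already-computed rate (for example a published table entry) in the
#' `release_rate` structure so it can flow through [toc_rate()],
#' [predict_enrichment()] and friends.
#'
#' @param analyte Analyte name.
#' @param rate Rate in umol (mg dry mass)^-1 d^-1.
#' @param sd Standard deviation (optional).
#' @param n_replicates Number of replicates behind the value.
#' @export
as_release_rate <- function(analyte, rate, sd = NA_real_, n_replicates = NA_integer_) {
  structure(list(analyte = analyte, rate = rate, sd = sd,
                 n_replicates = n_replicates, method = "supplied",
                 replicate_rates = rate, negative = rate < 0),
            class = "release_rate")
}

#' @export
print.release_rate <- function(x, ...) {
  cat(sprintf("%s release: %.3g umol (mg DM)^-1 d^-1", x$analyte, x$rate))
  if (!is.na(x$sd)) cat(sprintf(" (sd %.3g, n = %d)", x$sd, x$n_replicates))
  cat(sprintf(" [%s]\n", x$method))
  invisible(x)
}

#' Total organic carbon release: POC + DOC
#'
#' Rates add; standard deviations combine in quadrature.
#'
#' @param poc,doc `release_rate` objects for POC and DOC (same units).
#' @return A `release_rate` for analyte `"TOC"`.
#' @export
toc_rate <- function(poc, doc) {
  stopifnot(inherits(poc, "release_rate"), inherits(doc, "release_rate"))
  if (!identical(toupper(poc$analyte), "POC") ||
      !identical(toupper(doc$analyte), "DOC")) {
    stop("toc_rate() expects a POC and a DOC rate, got ",
         poc$analyte, " + ", doc$analyte, call. = FALSE)
  }
  sd <- if (is.na(poc$sd) && is.na(doc$sd)) NA_real_ else {
    sqrt(sum(c(poc$sd, doc$sd)^2, na.rm = TRUE))
  }
  as_release_rate("TOC", poc$rate + doc$rate, sd = sd,
                  n_replicates = min(poc$n_replicates, doc$n_replicates))
}

#' TOC release as percent of dry mass per day
#'
#' `umol_to_ug(rate, "C") / 1000 * 100`: a rate of 0.86 umol C mg^-1 d^-1
#' corresponds to about 1% of the dry mass leaching away per day.
#'
#' @param toc A `release_rate` (umol C mg^-1 d^-1) or bare numeric rate.
#' @return Percent of dry mass released per day.
#' @export
toc_percent_of_dm <- function(toc) {
  rate <- if (inherits(toc, "release_rate")) toc$rate else toc
  if (rate < 0) warning("negative TOC rate")
  umol_to_ug(rate, "C") / 1000 * 100
}

#' Partition dissolved inorganic nitrogen into its species
#'
#' DIN = NH4+ + NO3- + NO2-; returns the total and each species' percentage
#' share of DIN (shares sum to 100).
#'
#' @param nh4,no3,no2 Species rates or concentrations (>= 0, same units).
#' @return List with `din_total` and named `shares_pct`.
#' @export
din_partition <- function(nh4, no3, no2) {
  species <- c(NH4 = nh4, NO3 = no3, NO2 = no2)
  if (any(species < 0)) stop("DIN species must be >= 0", call. = FALSE)
  total <- sum(species)
  if (total == 0) stop("all DIN species are zero: shares undefined", call. = FALSE)
  list(din_total = total, shares_pct = 100 * species / total)
}

#' Low-molecular-weight share of a dissolved pool
#'
#' Percentage of a pool below the 1,000 Da dialysis cut-off.
#'
#' @param dialyzate_pool Pool measured in the dialyzate (< 1,000 Da).
#' @param total_pool Total pool (> 0).
#' @return Percent of the total pool that is LMW.
#' @export
lmw_fraction <- function(dialyzate_pool, total_pool) {
  if (any(total_pool <= 0)) stop("total pool must be > 0", call. = FALSE)
  100 * dialyzate_pool / total_pool
}

#' Predict the dissolved enrichment from an amendment
#'
#' Multiplies a per-dry-mass release rate by an amendment dose: a rate of
#' 0.44 umol DOC mg^-1 d^-1 and 100 mg jelly-DM L^-1 predict 44 umol DOC L^-1.
#'
#' @param rate A `release_rate` or bare numeric (umol mg^-1 d^-1).
#' @param amendment_mg_per_L Dry-mass dose, mg L^-1 (> 0).
#' @return Predicted concentration, umol L^-1.
#' @export
predict_enrichment <- function(rate, amendment_mg_per_L) {
  stopifnot(amendment_mg_per_L >= 0)
  r <- if (inherits(rate, "release_rate")) rate$rate else rate
  r * amendment_mg_per_L
}

#' Organic-matter load of a decaying jellyfish bloom
#'
#' @param individuals_per_m3 Bloom density, individuals m^-3 (>= 0).
#' @param dm_per_individual_g Dry mass per individual, g (> 0).
#' @param c_wt_fraction Carbon weight fraction of the dry mass (default 0.02).
#' @return List with `dm_g_per_m3` and `c_g_per_m3`.
#' @examples
#' bloom_load(10, 10) # 100 g DM m^-3, 2 g C m^-3
#' @export
bloom_load <- function(individuals_per_m3, dm_per_individual_g,
                       c_wt_fraction = 0.02) {
  stopifnot(individuals_per_m3 >= 0, dm_per_individual_g > 0,
            c_wt_fraction > 0)
  dm <- individuals_per_m3 * dm_per_individual_g
  list(dm_g_per_m3 = dm, c_g_per_m3 = dm * c_wt_fraction)
}

#' Release-rate table for every analyte in a leaching series
#'
#' Applies [release_rate()] per analyte and returns a table with the two
#' customary unit columns (umol and ug per mg dry mass per day; the ug column
#' only for C/N/P-convertible analytes). Internal consistency -- DON =
#' TDN - DIN and DIN = NH4 + NO3 + NO2 within tolerance -- is checked when
#' the analytes are present.
#'
#' @param series Tidy leaching series with one or more analytes.
#' @param setup A [leaching_setup()].
#' @param method Passed to [release_rate()].
#' @param elements Named map analyte -> element for the ug column.
#' @param tol Relative tolerance for the consistency checks.
#' @return A data frame with columns `analyte`, `rate_umol_per_mg_per_d`,
#'   `sd`, `n_replicates`, `rate_ug_per_mg_per_d`, `method`.
#' @export
release_rate_table <- function(series, setup = leaching_setup(),
                               method = c("ols", "endpoint"),
                               elements = c(POC = "C", DOC = "C", TOC = "C",
                                            PN = "N", TDN = "N", DON = "N",
                                            DIN = "N", NH4 = "N", NO3 = "N",
                                            NO2 = "N", PO4 = "P"),
                               tol = 0.05) {
  method <- match.arg(method)
  validate_series(series)
  rates <- lapply(split(series, series$analyte), release_rate,
                  setup = setup, method = method)
  tab <- do.call(rbind, lapply(rates, function(r) {
    el <- if (r$analyte %in% names(elements)) elements[[r$analyte]] else NA_character_
    data.frame(analyte = r$analyte,
               rate_umol_per_mg_per_d = r$rate, sd = r$sd,
               n_replicates = r$n_replicates,
               rate_ug_per_mg_per_d = if (!is.na(el)) umol_to_ug(r$rate, el) else NA_real_,
               method = method, stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  check_rate_consistency(tab, tol = tol)
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## DON = TDN - DIN and DIN = NH4 + NO3 + NO2, within relative tolerance.
check_rate_consistency <- function(tab, tol = 0.05) {
  g <- function(a) tab$rate_umol_per_mg_per_d[match(a, tab$analyte)]
  rel_off <- function(x, y) abs(x - y) / max(abs(y), .Machine$double.eps)
  if (all(c("NH4", "NO3", "NO2", "DIN") %in% tab$analyte)) {
    if (rel_off(g("NH4") + g("NO3") + g("NO2"), g("DIN")) > tol) {
      warning("DIN != NH4 + NO3 + NO2 beyond tolerance")
    }
  }
  if (all(c("TDN", "DIN", "DON") %in% tab$analyte)) {
    if (rel_off(g("TDN") - g("DIN"), g("DON")) > tol) {
      warning("DON != TDN - DIN beyond tolerance")
    }
  }
  invisible(tab)
}
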