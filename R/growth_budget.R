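#' Detect the exponential growth window of a cell-abundance series
#'
#' Among all contiguous windows of at least three timepoints that end at or
#' before the abundance maximum, returns the window maximising the R^2 of
#' ln(cells) vs time. Ties (within 1e-9) are broken toward the longer window,
#' then the earlier start. A series with no growth (maximum at the first
#' point, or constant) is an error.
#'
#' @param series Tidy series ([ts_record()]) of a single replicate's cell
#'   counts, or a data frame with `time_h` and `value` columns; cells must be
#'   positive. Values below `detection_limit` are treated as missing.
#' @param detection_limit Counts at or below this are dropped (default 0).
#' @return A `growth_window` list: `t_start_h`, `t_end_h`, `n_points`,
#'   `mu_per_h` (slope of ln cells vs time), `r_squared`.
#' @export
detect_exponential_window <- function(series, detection_limit = 0) {
  t <- series$time_h; y <- series$value
  keep <- is.finite(y) & y > detection_limit
  t <- t[keep]; y <- y[keep]
  o <- order(t); t <- t[o]; y <- y[o]
  if (length(t) < 4L) stop("need >= 4 timepoints to detect a growth window",
                           call. = FALSE)
  imax <- which.max(y)
  if (imax < 3L) stop("no growth detected: abundance maximum too early",
                      call. = FALSE)
  if (all(diff(y) <= 0)) stop("no growth detected: series is non-increasing",
                              call. = FALSE)
  ly <- log(y)
  best <- NULL
  for (i in 1:(imax - 2L)) {
    for (j in (i + 2L):imax) {
      fit <- ols_fit(t[i:j], ly[i:j])
      if (is.na(fit$r2)) next                       # constant segment
      len <- t[j] - t[i]
      better <- is.null(best) ||
        fit$r2 > best$r2 + 1e-9 ||
        (abs(fit$r2 - best$r2) <= 1e-9 &&
           (len > best$len + 1e-12 ||
              (abs(len - best$len) <= 1e-12 && t[i] < best$t0)))
      if (better) {
        best <- list(i = i, j = j, r2 = fit$r2, mu = fit$slope,
                     len = len, t0 = t[i])
      }
    }
  }
  if (is.null(best)) stop("no growth window found", call. = FALSE)
  growth_window(t_start_h = t[best$i], t_end_h = t[best$j],
                n_points = best$j - best$i + 1L,
                mu_per_h = best$mu, r_squared = best$r2)
}

#' Construct a growth window
#'
#' @param t_start_h,t_end_h Window bounds in hours (`t_end_h > t_start_h`).
#' @param n_points Number of timepoints in the window (>= 3, or 2 when built
#'   by hand from endpoints).
#' @param mu_per_h Slope of ln(cells) vs time, h^-1.
#' @param r_squared Fit R^2 in `[0, 1]` (NA when supplied by hand).
#' @export
growth_window <- function(t_start_h, t_end_h, n_points = 2L,
                          mu_per_h = NA_real_, r_squared = NA_real_) {
  stopifnot(t_end_h > t_start_h)
  if (!is.na(r_squared)) stopifnot(r_squared >= 0, r_squared <= 1 + 1e-12)
  structure(list(t_start_h = t_start_h, t_end_h = t_end_h,
                 n_points = as.integer(n_points), mu_per_h = mu_per_h,
                 r_squared = r_squared), class = "growth_window")
}

#' Community growth rate from a window
#'
#' @param window A `growth_window` with `mu_per_h` set.
#' @return List with `mu_per_h` and `mu_per_d` (= 24 x mu_per_h).
#' @export
growth_rate <- function(window) {
  stopifnot(inherits(window, "growth_window"), is.finite(window$mu_per_h))
  list(mu_per_h = window$mu_per_h, mu_per_d = 24 * window$mu_per_h)
}

#' Bacterial carbon budget of one batch-culture flask
#'
#' Over the exponential window, bacterial carbon demand (BCD) is the negated
#' rate of DOC change (umol C L^-1 h^-1 converted to ug C L^-1 h^-1 at
#' 12.011 g mol^-1); bacterial production (BP) is the rate of cell increase
#' converted at `fg_c_per_cell`; respiration BR = BCD - BP and growth
#' efficiency BGE = 100 BP/BCD follow exactly. When the DOC rate is
#' non-negative the budget is flagged `no_net_consumption` and BGE is `NA`.
#'
#' @param doc Tidy DOC series for the flask, umol C L^-1.
#' @param cells Tidy cell series for the flask, cells mL^-1.
#' @param window A `growth_window`; both series must cover it with >= 2
#'   points inside.
#' @param fg_c_per_cell Per-cell carbon, fg (default 19.8).
#' @param method `"ols"` (default) or `"endpoint"` rate estimation.
#' @param replicate_id Flask identifier carried into the result.
#' @return A `carbon_budget` list: `replicate_id`, `bcd_ugC_L_h`,
#'   `bp_ugC_L_h`, `br_ugC_L_h`, `bge_pct`, `mu_per_h`, `bb_ugC_L` (biomass
#'   carbon at window end), `method`, `flags`.
#' @export
carbon_budget <- function(doc, cells, window,
                          fg_c_per_cell = default_fg_c_per_cell,
                          method = c("ols", "endpoint"),
                          replicate_id = NA_character_) {
  method <- match.arg(method)
  stopifnot(inherits(window, "growth_window"))
  in_win <- function(df) {
    sel <- df$time_h >= window$t_start_h - 1e-9 &
      df$time_h <= window$t_end_h + 1e-9
    out <- df[sel, , drop = FALSE]
    if (nrow(out) < 2L) {
      stop("series does not cover the growth window", call. = FALSE)
    }
    out[order(out$time_h), ]
  }
  doc_w <- in_win(doc); cells_w <- in_win(cells)
  cells_per_L <- cells_w$value * 1000                    # cells/mL -> cells/L
  doc_slope <- slope_per_h(doc_w$time_h, doc_w$value, method)    # umol/L/h
  cell_slope <- slope_per_h(cells_w$time_h, cells_per_L, method) # cells/L/h
  mu <- if (is.finite(window$mu_per_h)) window$mu_per_h else {
    ols_fit(cells_w$time_h, log(cells_per_L))$slope
  }
  bcd <- -doc_slope * atomic_masses[["C"]]               # ug C / L / h
  bp <- cells_to_carbon(cell_slope, fg_c_per_cell)
  ## slopes of a constant series carry ~1e-17 numeric noise; treat as zero
  if (abs(bcd) < 1e-9) bcd <- 0
  flags <- character(0)
  if (bcd <= 0) flags <- c(flags, "no_net_consumption")
  bge <- if (bcd > 0) 100 * bp / bcd else NA_real_
  if (!is.na(bge) && bge > 100) flags <- c(flags, "bge_above_100")
  structure(list(
    replicate_id = replicate_id,
    bcd_ugC_L_h = bcd, bp_ugC_L_h = bp, br_ugC_L_h = bcd - bp,
    bge_pct = bge, mu_per_h = mu,
    bb_ugC_L = cells_to_carbon(cells_per_L[length(cells_per_L)], fg_c_per_cell),
    method = method, flags = flags
  ), class = "carbon_budget")
}

budget_quantities <- c("bcd_ugC_L_h", "bb_ugC_L", "mu_per_h",
                       "bp_ugC_L_h", "br_ugC_L_h", "bge_pct")

#' Aggregate replicate carbon budgets and compare against controls
#'
#' Each budget quantity (BCD, BB, mu, BP, BR, BGE) is averaged across
#' replicate flasks -- mean of per-replicate values, so the treatment BGE is
#' the mean of replicate-level ratios, not the ratio of mean BP to mean BCD
#' -- with SD, plus a pooled-variance two-sample t-test against the control
#' replicates.
#'
#' @param budgets List of `carbon_budget` objects (treatment replicates,
#'   >= 2).
#' @param control Optional list of `carbon_budget` objects for the control
#'   arm; when supplied, p-values are computed per quantity.
#' @param treatment Label for the treatment arm.
#' @return A `data.frame` with one row per quantity: treatment mean, sd, n,
#'   control mean, sd, n, and `p_value`.
#' @export
aggregate_budgets <- function(budgets, control = NULL, treatment = "jelly") {
  pull <- function(bs, q) vapply(bs, function(b) b[[q]], numeric(1))
  if (length(budgets) < 2L) {
    stop("need >= 2 replicates to aggregate (SD undefined otherwise)",
         call. = FALSE)
  }
  rows <- lapply(budget_quantities, function(q) {
    a <- pull(budgets, q)
    row <- data.frame(quantity = q, treatment = treatment,
                      mean = mean(a, na.rm = TRUE), sd = sd(a[!is.na(a)]),
                      n = sum(!is.na(a)),
                      control_mean = NA_real_, control_sd = NA_real_,
                      control_n = NA_integer_, p_value = NA_real_,
                      stringsAsFactors = FALSE)
    if (!is.null(control)) {
      b <- pull(control, q)
      row$control_mean <- mean(b, na.rm = TRUE)
      row$control_sd <- sd(b[!is.na(b)])
      row$control_n <- sum(!is.na(b))
      if (sum(!is.na(a)) >= 2L && sum(!is.na(b)) >= 2L) {
        row$p_value <- two_sample_t_test(a[!is.na(a)], b[!is.na(b)])$p
      }
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pooled-variance two-sample t-test
#'
#' Two-sided Student's t-test assuming homoscedasticity, df = n_a + n_b - 2.
#' Degenerate zero-variance inputs follow the conventions: equal means give
#' p = 1; unequal means give p = 0 with a warning.
#'
#' @param a,b Numeric vectors, each with >= 2 values.
#' @param var_equal Pooled variance (default, `TRUE`) or Welch (`FALSE`).
#' @return List with `t`, `df`, `p`.
#' @export
two_sample_t_test <- function(a, b, var_equal = TRUE) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  na <- length(a); nb <- length(b)
  va <- var(a); vb <- var(b)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    df <- na + nb - 2
    se <- sqrt(sp2 * (1 / na + 1 / nb))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  dm <- mean(a) - mean(b)
  if (se == 0) {
    if (dm == 0) return(list(t = 0, df = df, p = 1))
    warning("zero pooled variance with unequal means: p = 0 by convention")
    return(list(t = sign(dm) * Inf, df = df, p = 0))
  }
  t <- dm / se
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}
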