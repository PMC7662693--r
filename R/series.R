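#' Build a tidy measurement time series
#'
#' The package's common exchange format: one measurement per row with columns
#' `experiment`, `replicate`, `treatment`, `time_h`, `analyte`, `value`,
#' `unit`. All analysis functions consume and produce this shape.
#'
#' @param time_h Sampling times in hours.
#' @param value Measured values.
#' @param analyte Analyte name (e.g. `"DOC"`, `"cells"`, `"DFAA"`).
#' @param unit Measurement unit (e.g. `"umol/L"`, `"cells/mL"`).
#' @param replicate,treatment,experiment Identifiers (recycled).
#' @return A `data.frame` with the seven canonical columns.
#' @export
ts_record <- function(time_h, value, analyte, unit = "umol/L",
                      replicate = "R1", treatment = "jelly",
                      experiment = "I") {
  stopifnot(length(time_h) == length(value))
  n <- length(time_h)
  data.frame(
    experiment = rep_len(experiment, n), replicate = rep_len(replicate, n),
    treatment = rep_len(treatment, n), time_h = as.numeric(time_h),
    analyte = rep_len(analyte, n), value = as.numeric(value),
    unit = rep_len(unit, n),
    stringsAsFactors = FALSE
  )
}

series_columns <- c("experiment", "replicate", "treatment",
                    "time_h", "analyte", "value", "unit")

#' Validate a tidy time-series data frame
#'
#' Checks the canonical columns are present, times are finite, and (optionally)
#' that a single unit is used per analyte. Called by every analysis entry
#' point; exported for use on externally prepared tables.
#'
#' @param series A data frame as produced by [ts_record()] or [read_series()].
#' @return The validated data frame, invisibly.
#' @export
validate_series <- function(series) {
  missing <- setdiff(series_columns, names(series))
  if (length(missing)) {
    stop("series is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(series) == 0L) stop("series is empty", call. = FALSE)
  stopifnot(is.numeric(series$time_h), is.numeric(series$value))
  if (any(!is.finite(series$time_h))) stop("non-finite time_h", call. = FALSE)
  units <- tapply(series$unit, series$analyte, function(u) length(unique(u)))
  if (any(units > 1)) {
    stop("mixed units within analyte(s): ",
         paste(names(units)[units > 1], collapse = ", "), call. = FALSE)
  }
  invisible(series)
}

#' Read / write tidy time-series CSV
#'
#' @param path CSV file with the canonical columns of [ts_record()].
#' @return `read_series()` returns the validated data frame.
#' @export
read_series <- function(path) {
  validate_series(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_series
#' @param series Data frame to write.
#' @export
write_series <- function(series, path) {
  validate_series(series)
  write.csv(series, path, row.names = FALSE)
  invisible(path)
}

## --- internal slope machinery ------------------------------------------------

## OLS slope of y on x; returns list(slope, intercept, r2, n).
## r2 is NA when y is constant (zero total sum of squares).
ols_fit <- function(x, y) {
  n <- length(x)
  stopifnot(n >= 2L, length(y) == n)
  fit <- lm(y ~ x)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(residuals(fit)^2) / ss_tot else NA_real_
  list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       r2 = r2, n = n)
}

## Endpoint slope: (last - first) / (t_last - t_first), on time-sorted data.
endpoint_slope <- function(x, y) {
  o <- order(x)
  x <- x[o]; y <- y[o]
  n <- length(x)
  if (x[n] == x[1L]) stop("endpoint slope undefined: zero time span", call. = FALSE)
  (y[n] - y[1L]) / (x[n] - x[1L])
}

## Slope per hour by either method over (time-sorted) points.
slope_per_h <- function(time_h, value, method = c("ols", "endpoint")) {
  method <- match.arg(method)
  o <- order(time_h)
  time_h <- time_h[o]; value <- value[o]
  if (method == "endpoint") endpoint_slope(time_h, value) else ols_fit(time_h, value)$slope
}

## Pick the contiguous prefix (>= 3 points, or all points if fewer) maximising
## OLS R^2; ties (within 1e-9) broken toward the longer prefix. Used for
## saturating leaching curves. Returns indices into the time-sorted series.
best_prefix <- function(time_h, value, min_points = 3L) {
  n <- length(time_h)
  if (n <= min_points) return(seq_len(n))
  best <- seq_len(n); best_r2 <- -Inf
  for (j in n:min_points) {           # longer prefixes first -> ties go long
    r2 <- ols_fit(time_h[1:j], value[1:j])$r2
    if (!is.na(r2) && r2 > best_r2 + 1e-9) {
      best_r2 <- r2; best <- 1:j
    }
  }
  best
}
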