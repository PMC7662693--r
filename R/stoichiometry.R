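#' Atomic masses used throughout the package
#'
#' Fixed IUPAC values (g mol^-1) for the three elements the package converts:
#' C = 12.011, N = 14.007, P = 30.974. Kept as a named constant so every
#' umol <-> ug conversion in the package uses the same masses.
#'
#' @format Named numeric vector of length 3.
#' @export
atomic_masses <- c(C = 12.011, N = 14.007, P = 30.974)

#' Default per-cell carbon content
#'
#' Carbon conversion factor for marine bacterioplankton, 19.8 fg C cell^-1,
#' used to turn cell abundances into biomass carbon.
#'
#' @format Numeric scalar (fg C cell^-1).
#' @export
default_fg_c_per_cell <- 19.8

#' Convert micromoles of an element to micrograms
#'
#' @param amount Amount in umol. Finite numeric (vectorised).
#' @param element One of `"C"`, `"N"`, `"P"`.
#' @return Amount in ug (`amount * atomic mass`).
#' @examples
#' umol_to_ug(0.86, "C") # 10.329
#' @export
umol_to_ug <- function(amount, element) {
  if (length(element) != 1L || !element %in% names(atomic_masses)) {
    stop("unknown element symbol: ", paste(element, collapse = ", "),
         " (expected one of C, N, P)", call. = FALSE)
  }
  stopifnot(is.numeric(amount), all(is.finite(amount)))
  amount * atomic_masses[[element]]
}

#' Molar C:N ratio from weight percentages
#'
#' Converts carbon and nitrogen weight fractions of dry mass to a molar ratio
#' `(c/12.011)/(n/14.007)`. Full precision is returned; display rounding to
#' one decimal is left to the caller (see [worked_example_report()]).
#'
#' @param c_wt_pct Carbon content, % of dry mass (> 0).
#' @param n_wt_pct Nitrogen content, % of dry mass (> 0).
#' @return Dimensionless molar C:N ratio.
#' @examples
#' molar_cn(26.5, 6.7) # 4.61 -> prints as 4.6
#' @export
molar_cn <- function(c_wt_pct, n_wt_pct) {
  stopifnot(is.numeric(c_wt_pct), is.numeric(n_wt_pct))
  if (any(n_wt_pct == 0)) stop("n_wt_pct is zero: molar C:N undefined", call. = FALSE)
  if (any(c_wt_pct <= 0) || any(n_wt_pct < 0)) {
    stop("weight percentages must be positive", call. = FALSE)
  }
  (c_wt_pct / atomic_masses[["C"]]) / (n_wt_pct / atomic_masses[["N"]])
}

#' Convert cell abundance to biomass carbon
#'
#' @param cells Cell abundance in cells L^-1 (>= 0, vectorised).
#' @param fg_c_per_cell Carbon content per cell in fg C (default 19.8).
#' @return Biomass carbon in ug C L^-1 (`cells * fg_c_per_cell * 1e-9`).
#' @examples
#' cells_to_carbon(1e9) # 19.8 ug C / L
#' @export
cells_to_carbon <- function(cells, fg_c_per_cell = default_fg_c_per_cell) {
  stopifnot(is.numeric(cells), fg_c_per_cell > 0)
  if (any(cells < 0, na.rm = TRUE)) stop("negative cell abundance", call. = FALSE)
  cells * fg_c_per_cell * 1e-9
}

#' Percentage of a pool consumed between two measurements
#'
#' `100 * (initial - final) / initial`. Negative values (net accumulation)
#' are allowed -- noisy pools can grow -- but raise a warning rather than
#' being clamped.
#'
#' @param initial Initial pool size (> 0).
#' @param final Final pool size (>= 0).
#' @return Percentage of the initial pool consumed.
#' @examples
#' fraction_consumed(203.45, 5.56) # 97.27
#' @export
fraction_consumed <- function(initial, final) {
  stopifnot(is.numeric(initial), is.numeric(final))
  if (any(initial <= 0)) stop("initial pool must be > 0", call. = FALSE)
  if (any(final < 0)) stop("final pool must be >= 0", call. = FALSE)
  out <- 100 * (initial - final) / initial
  if (any(out < 0)) warning("net accumulation: fraction_consumed() is negative")
  out
}
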