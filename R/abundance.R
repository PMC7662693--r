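#' Reads-per-million normalisation of mapped-read counts
#'
#' `RPM = 1e6 * (mapped_reads / length) / sum(mapped_reads / length)` within
#' each sample. Length-normalising first removes the advantage long features
#' have in recruiting reads; the renormalisation makes every sample sum to
#' exactly one million. Features with zero reads get RPM 0 and stay in the
#' table (downstream joins need them).
#'
#' @param features Data frame with columns `feature_id`, `length`,
#'   `mapped_reads`, and optionally `sample_id` (normalisation is per
#'   sample).
#' @return The input with an `rpm` column appended.
#' @export
rpm <- function(features) {
  stopifnot(all(c("feature_id", "length", "mapped_reads") %in% names(features)))
  if (any(features$length <= 0)) stop("feature length must be > 0", call. = FALSE)
  if (any(features$mapped_reads < 0)) stop("negative read counts", call. = FALSE)
  if (!"sample_id" %in% names(features)) features$sample_id <- "sample1"
  out <- do.call(rbind, lapply(split(features, features$sample_id), function(df) {
    w <- df$mapped_reads / df$length
    if (sum(w) <= 0) stop("all-zero read counts in sample ", df$sample_id[1L],
                          call. = FALSE)
    df$rpm <- 1e6 * w / sum(w)
    df
  }))
  rownames(out) <- NULL
  out
}

#' Relative abundance of MAGs from their RPM values
#'
#' Percentage of each metagenome-assembled genome: its RPM divided by the sum
#' of RPM over all MAGs, times 100. Percentages sum to 100.
#'
#' @param mag_rpm Named numeric vector of per-MAG RPM (or any
#'   RPM-proportional values) for one sample.
#' @return Named numeric vector of percentages.
#' @export
mag_relative_abundance <- function(mag_rpm) {
  stopifnot(is.numeric(mag_rpm), length(mag_rpm) >= 1L)
  total <- sum(mag_rpm)
  if (total <= 0) stop("sum of MAG RPM must be > 0", call. = FALSE)
  100 * mag_rpm / total
}

#' FISH population count
#'
#' @param taxon Taxon or probe name.
#' @param fraction_of_total Fraction of DAPI-stained cells in `[0, 1]`.
#' @param total_cells Total cell abundance, cells mL^-1 (>= 0).
#' @return A `population_count` list.
#' @export
population_count <- function(taxon, fraction_of_total, total_cells) {
  stopifnot(fraction_of_total >= 0, fraction_of_total <= 1, total_cells >= 0)
  structure(list(taxon = taxon, fraction_of_total = fraction_of_total,
                 total_cells = total_cells), class = "population_count")
}

#' Absolute abundance of a FISH-identified population
#'
#' @param pop A [population_count()].
#' @return Cells mL^-1 (`fraction * total`).
#' @export
population_absolute <- function(pop) {
  stopifnot(inherits(pop, "population_count"))
  pop$fraction_of_total * pop$total_cells
}

#' Fold change of a population across an incubation, accounting for dilution
#'
#' The inoculum is diluted into the incubation (default 1:10, the 9:1
#' aged-seawater:inoculum setup), so the reference abundance is the initial
#' absolute abundance divided by `dilution_factor`:
#' `fold = final / (initial / dilution_factor)`.
#'
#' @param initial,final [population_count()] objects.
#' @param dilution_factor Dilution of the inoculum into the incubation
#'   (default 10).
#' @return Fold change (numeric scalar).
#' @export
fold_change <- function(initial, final, dilution_factor = 10) {
  stopifnot(dilution_factor > 0)
  init_abs <- population_absolute(initial)
  if (init_abs <= 0) stop("initial population is zero: fold change undefined",
                          call. = FALSE)
  population_absolute(final) / (init_abs / dilution_factor)
}

#' Read a mapped-read count table
#'
#' @param path TSV with columns `sample_id`, `feature_id`, `length`
#'   (or `length_bp`), `mapped_reads`.
#' @return Data frame of feature counts.
#' @export
read_feature_counts <- function(path) {
  df <- read.csv(path, sep = "\t", stringsAsFactors = FALSE)
  if ("length_bp" %in% names(df) && !"length" %in% names(df)) {
    df$length <- df$length_bp
  }
  need <- c("feature_id", "length", "mapped_reads")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("feature-count table missing columns: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  df
}
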