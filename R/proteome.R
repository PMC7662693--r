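#' PSMs per amino-acid residue
#'
#' Peptide spectrum matches divided by the protein's residue count: a
#' label-free proxy for absolute peptide abundance that removes the trivial
#' advantage long proteins have in accumulating matches.
#'
#' @param psms PSM count (>= 0, vectorised).
#' @param aa_length Protein length in residues (> 0).
#' @return PSMs/AA abundance proxy.
#' @export
psm_per_aa <- function(psms, aa_length) {
  stopifnot(is.numeric(psms), is.numeric(aa_length))
  if (any(aa_length <= 0)) stop("aa_length must be > 0", call. = FALSE)
  if (any(psms < 0)) stop("psms must be >= 0", call. = FALSE)
  psms / aa_length
}

#' Total PSMs/AA pool at one timepoint
#'
#' Sum of PSMs/AA over all proteins detected at a timepoint; an empty table
#' is a zero pool. A duplicated `protein_id` within the timepoint is
#' ambiguous and rejected.
#'
#' @param records Data frame with columns `protein_id`, `aa_length`, `psms`
#'   for a single timepoint.
#' @return Total PSMs/AA (numeric scalar).
#' @export
pool_total <- function(records) {
  if (is.null(records) || nrow(records) == 0L) return(0)
  if (anyDuplicated(records$protein_id)) {
    stop("duplicate protein_id at one timepoint: ",
         paste(unique(records$protein_id[duplicated(records$protein_id)]),
               collapse = ", "), call. = FALSE)
  }
  sum(psm_per_aa(records$psms, records$aa_length))
}

#' Percentage of the protein pool consumed between two timepoints
#'
#' Delegates to [fraction_consumed()] on pool totals; invariant to any common
#' rescaling of all PSMs at both timepoints.
#'
#' @param t0_total Pool total at the start (> 0).
#' @param t_total Pool total at the later timepoint.
#' @return Percent of the initial pool consumed.
#' @examples
#' pool_consumed_pct(203.45, 5.56) # 97.27
#' @export
pool_consumed_pct <- function(t0_total, t_total) {
  fraction_consumed(t0_total, t_total)
}

#' Per-protein relative abundance with a reporting floor
#'
#' For each timepoint, every protein's share (%) of the timepoint's total
#' PSMs/AA. Proteins never exceeding `report_floor_pct` at any timepoint are
#' rolled into an `"others"` row in the report; the floor affects reporting
#' only -- pool totals and the returned `rel_pct` are computed over all
#' proteins. Proteins absent from a timepoint are treated as psms = 0.
#'
#' @param records Data frame with `protein_id`, `annotation`, `aa_length`,
#'   `psms`, `timepoint_h` (several timepoints allowed).
#' @param report_floor_pct Reporting floor, percent (default 1).
#' @return List with `table` (long data frame: `timepoint_h`, `protein_id`,
#'   `annotation`, `psm_per_aa`, `rel_pct`), `report` (floor-filtered, with
#'   `"others"`), and `totals` (named per-timepoint pool totals).
#' @export
relative_abundance_table <- function(records, report_floor_pct = 1.0) {
  stopifnot(all(c("protein_id", "aa_length", "psms", "timepoint_h") %in%
                  names(records)))
  if (!"annotation" %in% names(records)) records$annotation <- records$protein_id
  tps <- sort(unique(records$timepoint_h))
  long <- do.call(rbind, lapply(tps, function(tp) {
    at_tp <- records[records$timepoint_h == tp, ]
    total <- pool_total(at_tp)
    if (total <= 0) stop("zero PSMs/AA total at timepoint ", tp, call. = FALSE)
    ppa <- psm_per_aa(at_tp$psms, at_tp$aa_length)
    data.frame(timepoint_h = tp, protein_id = at_tp$protein_id,
               annotation = at_tp$annotation, psm_per_aa = ppa,
               rel_pct = 100 * ppa / total, stringsAsFactors = FALSE)
  }))
  totals <- vapply(split(records, records$timepoint_h), pool_total, numeric(1))
  ## reporting: keep proteins above the floor at >= 1 timepoint
  max_rel <- tapply(long$rel_pct, long$protein_id, max)
  keep_ids <- names(max_rel)[max_rel > report_floor_pct]
  kept <- long[long$protein_id %in% keep_ids, ]
  folded <- long[!long$protein_id %in% keep_ids, ]
  if (nrow(folded)) {
    others <- do.call(rbind, lapply(split(folded, folded$timepoint_h), function(df) {
      data.frame(timepoint_h = df$timepoint_h[1L], protein_id = "others",
                 annotation = "others", psm_per_aa = sum(df$psm_per_aa),
                 rel_pct = sum(df$rel_pct), stringsAsFactors = FALSE)
    }))
    report <- rbind(kept, others)
  } else {
    report <- kept
  }
  report <- report[order(report$timepoint_h, -report$rel_pct), ]
  rownames(long) <- rownames(report) <- NULL
  list(table = long, report = report, totals = totals)
}

#' Roll protein abundances up into annotation categories
#'
#' Each protein maps to at most one category; unmapped proteins fall into
#' `"uncharacterized"`. Category shares sum to 100.
#'
#' @param records Single-timepoint data frame with `protein_id`, `aa_length`,
#'   `psms`.
#' @param category_map Named character vector or data frame
#'   (`protein_id`, `category`); may be empty.
#' @return Named numeric vector of category percentages.
#' @export
annotation_rollup <- function(records, category_map = character(0)) {
  total <- pool_total(records)
  if (total <= 0) stop("zero pool total", call. = FALSE)
  if (is.data.frame(category_map)) {
    category_map <- setNames(category_map$category, category_map$protein_id)
  }
  cat <- unname(category_map[records$protein_id])
  cat[is.na(cat)] <- "uncharacterized"
  ppa <- psm_per_aa(records$psms, records$aa_length)
  shares <- tapply(100 * ppa / total, cat, sum)
  out <- as.numeric(shares)
  names(out) <- names(shares)
  sort(out, decreasing = TRUE)
}

#' Read a PSM table
#'
#' @param path TSV with columns `protein_id`, `annotation`, `aa_length`,
#'   `psms`, `timepoint_h`.
#' @return Data frame of PSM records.
#' @export
read_psm_table <- function(path) {
  df <- read.csv(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("protein_id", "aa_length", "psms", "timepoint_h")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("PSM table missing columns: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  df
}
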