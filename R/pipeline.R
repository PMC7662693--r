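#' Build and validate a pipeline run configuration
#'
#' @param seed Integer seed for the simulators.
#' @param outdir Output directory for the report bundle.
#' @param method Rate-estimation method, `"ols"` or `"endpoint"`.
#' @param dilution_factor Inoculum dilution used by [fold_change()].
#' @param peak_h,stationary_end_h,end_h Growth-phase boundaries
#'   (see [phase_windows()]).
#' @param report_floor_pct Proteome reporting floor.
#' @param sim Named list of [sim_params()] overrides, applied when the
#'   pipeline simulates its inputs.
#' @param inputs Optional named list of input paths (`batch_csv`,
#'   `leaching_csv`, `psm_tsv`, `reads_tsv`); any path supplied replaces the
#'   corresponding simulation.
#' @return A validated `run_config` list. Unknown keys in `sim` or `inputs`
#'   are rejected.
#' @export
run_config <- function(seed = 1L, outdir = tempfile("jellyom_run_"),
                       method = c("ols", "endpoint"), dilution_factor = 10,
                       peak_h = 32, stationary_end_h = 46, end_h = 84,
                       report_floor_pct = 1,
                       sim = list(), inputs = list()) {
  method <- match.arg(method)
  allowed_inputs <- c("batch_csv", "leaching_csv", "psm_tsv", "reads_tsv")
  bad <- setdiff(names(inputs), allowed_inputs)
  if (length(bad)) stop("unknown input keys: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  bad_sim <- setdiff(names(sim), names(formals(sim_params)))
  if (length(bad_sim)) stop("unknown sim parameter(s): ",
                            paste(bad_sim, collapse = ", "), call. = FALSE)
  stopifnot(dilution_factor > 0, report_floor_pct >= 0)
  structure(list(seed = as.integer(seed), outdir = outdir, method = method,
                 dilution_factor = dilution_factor, peak_h = peak_h,
                 stationary_end_h = stationary_end_h, end_h = end_h,
                 report_floor_pct = report_floor_pct,
                 sim = sim, inputs = inputs), class = "run_config")
}

#' Read a run configuration from JSON
#'
#' @param path JSON file whose keys match the arguments of [run_config()].
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  bad <- setdiff(names(raw), names(formals(run_config)))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  do.call(run_config, raw)
}

## Per-replicate budgets for one treatment arm of one experiment. mu comes
## from the best-fit (max R^2) window; the carbon budget is computed over the
## full growth window -- first sample to abundance peak -- because the short
## max-R^2 window leaves too little DOC drawdown relative to measurement
## noise (the "DOC change during exponential growth" convention).
arm_budgets <- function(batch, experiment, treatment, method, fg_c_per_cell) {
  arm <- batch[batch$experiment == experiment & batch$treatment == treatment, ]
  lapply(split(arm, arm$replicate), function(df) {
    cells <- df[df$analyte == "cells", ]
    doc <- df[df$analyte == "DOC", ]
    fit <- detect_exponential_window(cells)
    t_peak <- cells$time_h[which.max(cells$value)]
    full <- growth_window(min(cells$time_h), t_peak,
                          n_points = sum(cells$time_h <= t_peak),
                          mu_per_h = fit$mu_per_h, r_squared = fit$r_squared)
    carbon_budget(doc, cells, full, fg_c_per_cell = fg_c_per_cell,
                  method = method,
                  replicate_id = paste(experiment, df$replicate[1L], sep = "/"))
  })
}

#' Run the full analysis pipeline
#'
#' Simulates (or reads) a leaching experiment, two batch-culture experiments,
#' a PSM table and a read-count table, then runs every analysis module and
#' writes a report bundle: `release_rates.csv`, `budget_summary.csv`,
#' `net_rates.csv`, `proteome_report.csv`, `mag_abundance.csv`, and a
#' machine-readable `summary.json` recording each derived quantity together
#' with the method that produced it. The bundle is a pure function of
#' (inputs, config, seed); any stage failure aborts with the stage name and
#' removes partial outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results and `outdir`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  fail <- function(stage, e) {
    unlink(written)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  emit <- function(df, name) {
    path <- file.path(config$outdir, name)
    write.csv(df, path, row.names = FALSE)
    written <<- c(written, path)
    path
  }
  params <- do.call(sim_params, c(list(seed = config$seed), config$sim))

  ## --- stage: inputs ---------------------------------------------------------
  dat <- tryCatch({
    leach <- if (!is.null(config$inputs$leaching_csv)) {
      read_series(config$inputs$leaching_csv)
    } else simulate_leaching(params)
    batch <- if (!is.null(config$inputs$batch_csv)) {
      read_series(config$inputs$batch_csv)
    } else rbind(simulate_batch_culture(params, "I"),
                 simulate_batch_culture(params, "II"))
    psm <- if (!is.null(config$inputs$psm_tsv)) {
      read_psm_table(config$inputs$psm_tsv)
    } else simulate_psm_table(params)
    reads <- if (!is.null(config$inputs$reads_tsv)) {
      read_feature_counts(config$inputs$reads_tsv)
    } else simulate_read_counts(params$mag_profile, seed = params$seed)
    list(leach = leach, batch = batch, psm = psm, reads = reads)
  }, error = function(e) fail("inputs", e))
  if (nrow(dat$batch) == 0L) {
    unlink(written)
    stop("pipeline stage 'inputs' failed: empty batch-culture input",
         call. = FALSE)
  }

  ## --- stage: leaching -------------------------------------------------------
  rates <- tryCatch(
    release_rate_table(dat$leach, method = config$method),
    error = function(e) fail("leaching", e))
  emit(rates, "release_rates.csv")

  ## --- stage: carbon budget --------------------------------------------------
  budgets <- tryCatch({
    experiments <- unique(dat$batch$experiment)
    jelly <- unlist(lapply(experiments, arm_budgets, batch = dat$batch,
                           treatment = "jelly", method = config$method,
                           fg_c_per_cell = params$fg_c_per_cell),
                    recursive = FALSE)
    control <- unlist(lapply(experiments, arm_budgets, batch = dat$batch,
                             treatment = "control", method = config$method,
                             fg_c_per_cell = params$fg_c_per_cell),
                      recursive = FALSE)
    list(jelly = jelly, control = control,
         summary = aggregate_budgets(jelly, control))
  }, error = function(e) fail("carbon budget", e))
  emit(budgets$summary, "budget_summary.csv")

  ## --- stage: amino-acid / nutrient pools ------------------------------------
  net <- tryCatch({
    phases <- phase_windows(config$peak_h, config$stationary_end_h, config$end_h)
    jelly <- dat$batch[dat$batch$treatment == "jelly", ]
    rows <- list()
    for (an in intersect(c("DFAA", "DCAA", "TDHAA", "NH4", "PO4", "TDN", "DON"),
                         unique(jelly$analyte))) {
      for (ph in names(phases)) {
        rr <- tryCatch(
          net_rate(jelly[jelly$analyte == an, ], phases[[ph]],
                   method = config$method, label = ph),
          error = function(e) NULL)   # phase not covered by this grid
        if (!is.null(rr)) {
          rows[[length(rows) + 1L]] <- data.frame(
            analyte = an, phase = ph, rate_per_h = rr$rate, sd = rr$sd,
            n = rr$n, unit = rr$unit_per_h, stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  }, error = function(e) fail("pools", e))
  emit(net, "net_rates.csv")

  ## --- stage: proteome -------------------------------------------------------
  prot <- tryCatch({
    rel <- relative_abundance_table(dat$psm, config$report_floor_pct)
    t0 <- min(dat$psm$timepoint_h)
    consumed <- vapply(
      setdiff(sort(unique(dat$psm$timepoint_h)), t0),
      function(tp) pool_consumed_pct(rel$totals[[as.character(t0)]],
                                     rel$totals[[as.character(tp)]]),
      numeric(1))
    names(consumed) <- setdiff(sort(unique(dat$psm$timepoint_h)), t0)
    list(rel = rel, consumed_pct = consumed)
  }, error = function(e) fail("proteome", e))
  emit(prot$rel$report, "proteome_report.csv")

  ## --- stage: community abundance --------------------------------------------
  comm <- tryCatch({
    counts <- rpm(dat$reads)
    rel <- mag_relative_abundance(setNames(counts$rpm, counts$feature_id))
    counts$relative_pct <- rel[counts$feature_id]
    counts
  }, error = function(e) fail("community abundance", e))
  emit(comm, "mag_abundance.csv")

  ## --- stage: summary --------------------------------------------------------
  summary_path <- file.path(config$outdir, "summary.json")
  tryCatch({
    pick <- function(q, col) {
      budgets$summary[budgets$summary$quantity == q, col]
    }
    summary <- list(
      seed = config$seed, method = config$method,
      units = list(budgets = "ugC/L/h", mu = "1/h",
                   release_rates = "umol/mg/d"),
      release_rates = setNames(as.list(rates$rate_umol_per_mg_per_d),
                               rates$analyte),
      mu_per_h = list(mean = pick("mu_per_h", "mean"),
                      sd = pick("mu_per_h", "sd")),
      bge_pct = list(mean = pick("bge_pct", "mean"),
                     sd = pick("bge_pct", "sd"),
                     aggregation = "mean of per-replicate BP/BCD ratios"),
      bcd_ugC_L_h = list(mean = pick("bcd_ugC_L_h", "mean"),
                         sd = pick("bcd_ugC_L_h", "sd")),
      protein_pool_consumed_pct = as.list(prot$consumed_pct),
      mag_relative_abundance_pct =
        as.list(setNames(comm$relative_pct, comm$feature_id)),
      net_rates = lapply(seq_len(nrow(net)), function(i) as.list(net[i, ]))
    )
    jsonlite::write_json(summary, summary_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    written <- c(written, summary_path)
  }, error = function(e) fail("summary", e))

  invisible(list(release_rates = rates, budgets = budgets, net_rates = net,
                 proteome = prot, community = comm, outdir = config$outdir))
}

#' Command-line interface
#'
#' Subcommands: `simulate` (write the synthetic tidy CSVs),
#' `pipeline` (run [run_pipeline()]), `worked-example` (print
#' [worked_example_report()]). Options: `--seed <int>`, `--outdir <dir>`,
#' `--config <json>` (pipeline only).
#'
#' @param args Character vector of CLI arguments (default
#'   `commandArgs(TRUE)`).
#' @return Exit status, invisibly (0 on success).
#' @export
jellyom_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: jellyom <simulate|pipeline|worked-example> [--seed N] [--outdir DIR] [--config FILE]"
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[[1L]]; rest <- args[-1L]
  opt <- function(flag, default) {
    i <- which(rest == flag)
    if (length(i) == 1L && i < length(rest)) rest[[i + 1L]] else default
  }
  seed <- as.integer(opt("--seed", "1"))
  outdir <- opt("--outdir", ".")
  switch(cmd,
    "simulate" = {
      p <- sim_params(seed = seed)
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      write_series(simulate_leaching(p), file.path(outdir, "leaching.csv"))
      batch <- rbind(simulate_batch_culture(p, "I"),
                     simulate_batch_culture(p, "II"))
      write_series(batch, file.path(outdir, "batch.csv"))
      write_ground_truth(batch, file.path(outdir, "ground_truth.json"))
      message("wrote leaching.csv, batch.csv, ground_truth.json to ", outdir)
    },
    "pipeline" = {
      cfg_path <- opt("--config", NA)
      cfg <- if (!is.na(cfg_path)) read_run_config(cfg_path) else
        run_config(seed = seed, outdir = outdir)
      run_pipeline(cfg)
      message("report bundle written to ", cfg$outdir)
    },
    "worked-example" = {
      print(worked_example_report(), row.names = FALSE)
    },
    { message("unknown subcommand: ", cmd, "\n", usage); return(invisible(1L)) }
  )
  invisible(0L)
}
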