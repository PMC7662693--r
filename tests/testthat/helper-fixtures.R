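# fixtures are built in code; nothing is read from disk

## linear concentration series: value = a + b * t
linear_series <- function(t, a, b, analyte = "DOC", replicate = "R1",
                          unit = "umol/L") {
  ts_record(t, a + b * t, analyte = analyte, replicate = replicate, unit = unit)
}

## exponential cell series in cells/mL
exp_cells <- function(t, n0 = 1e5, mu = 0.1, replicate = "R1") {
  ts_record(t, n0 * exp(mu * t), analyte = "cells", unit = "cells/mL",
            replicate = replicate)
}

## a carbon_budget object with prescribed quantities, for aggregation tests
fake_budget <- function(bcd, bp, mu = 0.09, bb = 200, id = "X") {
  structure(list(replicate_id = id, bcd_ugC_L_h = bcd, bp_ugC_L_h = bp,
                 br_ugC_L_h = bcd - bp, bge_pct = 100 * bp / bcd,
                 mu_per_h = mu, bb_ugC_L = bb, method = "ols",
                 flags = character(0)), class = "carbon_budget")
}

## per-replicate jelly budgets over the full 0..peak window, as the pipeline
## computes them (helper shared by recovery tests)
jelly_bge_mean <- function(params) {
  batch <- rbind(simulate_batch_culture(params, "I"),
                 simulate_batch_culture(params, "II"))
  bges <- unlist(lapply(c("I", "II"), function(e) {
    arm <- batch[batch$experiment == e & batch$treatment == "jelly", ]
    vapply(split(arm, arm$replicate), function(df) {
      cells <- df[df$analyte == "cells", ]
      doc <- df[df$analyte == "DOC", ]
      t_peak <- cells$time_h[which.max(cells$value)]
      win <- growth_window(min(cells$time_h), t_peak,
                           mu_per_h = params$mu_per_h)
      carbon_budget(doc, cells, win)$bge_pct
    }, numeric(1))
  }))
  mean(bges, na.rm = TRUE)
}

## mean detected growth rate across jelly replicates of both experiments
jelly_mu_mean <- function(params) {
  batch <- rbind(simulate_batch_culture(params, "I"),
                 simulate_batch_culture(params, "II"))
  mus <- unlist(lapply(c("I", "II"), function(e) {
    arm <- batch[batch$experiment == e & batch$treatment == "jelly" &
                   batch$analyte == "cells", ]
    vapply(split(arm, arm$replicate),
           function(df) detect_exponential_window(df)$mu_per_h, numeric(1))
  }))
  mean(mus)
}
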