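test_that("generators are deterministic given the seed", {
  p <- sim_params(seed = 123)
  expect_identical(simulate_leaching(p), simulate_leaching(p))
  expect_identical(simulate_batch_culture(p, "I"),
                   simulate_batch_culture(p, "I"))
  expect_identical(simulate_psm_table(p, noise = "poisson"),
                   simulate_psm_table(p, noise = "poisson"))
  expect_identical(simulate_read_counts(p$mag_profile, seed = 123),
                   simulate_read_counts(p$mag_profile, seed = 123))
  ## different seeds differ (noise is actually applied)
  expect_false(identical(simulate_batch_culture(sim_params(seed = 1), "I"),
                         simulate_batch_culture(sim_params(seed = 2), "I")))
})

test_that("leaching generator saturates and supports rate recovery", {
  ## noiseless, near-instant leaching: constant at the plateau
  p <- sim_params(seed = 1, noise_cv = 0, leach_k_per_h = 500)
  lf <- simulate_leaching(p, analyte_targets = c(DOC = 0.44))
  vals <- lf$value[lf$time_h > 0]
  expect_equal(vals, rep(110, length(vals)), tolerance = 1e-3)
  ## noiseless small k: OLS over the rising limb recovers k * plateau
  p2 <- sim_params(seed = 1, noise_cv = 0, leach_k_per_h = 0.005)
  lf2 <- simulate_leaching(p2, analyte_targets = c(DOC = 0.44))
  rr <- release_rate(lf2[lf2$replicate == "F1", ], leaching_setup(), "ols")
  want <- 0.005 * 110 * 24 / 250
  expect_equal(rr$rate, want, tolerance = 0.01)
  ## stochastic recovery at default noise vs the noiseless estimator
  truth <- release_rate(
    simulate_leaching(sim_params(seed = 1, noise_cv = 0),
                      analyte_targets = c(DOC = 0.44)),
    leaching_setup(), "endpoint")$rate
  errs <- vapply(1:100, function(s) {
    noisy <- simulate_leaching(sim_params(seed = s),
                               analyte_targets = c(DOC = 0.44))
    est <- release_rate(noisy, leaching_setup(), "endpoint")$rate
    abs(est - truth) / truth
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})

test_that("batch-culture generator has the programmed structure", {
  p <- sim_params(seed = 5, noise_cv = 0)
  b <- simulate_batch_culture(p, "II")
  j <- b[b$replicate == "J1", ]
  cells <- j[j$analyte == "cells", ]
  ## exponential to the peak, decay after
  expect_equal(cells$value[cells$time_h == 32], 5.7e5 * exp(0.09 * 32),
               tolerance = 1e-12)
  expect_lt(cells$value[cells$time_h == 84], cells$value[cells$time_h == 32])
  ## DOC drawdown stops at the peak
  doc <- j[j$analyte == "DOC", ]
  expect_equal(doc$value[doc$time_h == 56], doc$value[doc$time_h == 32])
  ## programmed NH4 slope is recovered exactly at zero noise
  nh4 <- j[j$analyte == "NH4", ]
  expect_equal(net_rate(nh4, c(0, 84))$rate, 0.29, tolerance = 1e-12)
  ## mu = 0 gives flat cells and flat DOC
  p0 <- sim_params(seed = 5, mu_per_h = 0, noise_cv = 0)
  b0 <- simulate_batch_culture(p0, "I")
  j0 <- b0[b0$replicate == "J1", ]
  expect_equal(var(j0$value[j0$analyte == "cells"]), 0)
  expect_equal(var(j0$value[j0$analyte == "DOC"]), 0)
  ## TDHAA = DFAA + DCAA in the noiseless truth
  expect_equal(j$value[j$analyte == "TDHAA"],
               j$value[j$analyte == "DFAA"] + j$value[j$analyte == "DCAA"])
  ## DFAA is consumed before DCAA: DCAA flat early
  dcaa_j <- j[j$analyte == "DCAA", ]
  expect_equal(dcaa_j$value[dcaa_j$time_h == 32],
               dcaa_j$value[dcaa_j$time_h == 0])
  expect_lt(dcaa_j$value[dcaa_j$time_h == 84],
            dcaa_j$value[dcaa_j$time_h == 46])
  expect_error(simulate_batch_culture(sim_params(bge = 0)), "bge")
})

test_that("zero-noise closure returns programmed mu and BGE to < 1e-9", {
  for (bge in c(0.2, 0.65, 0.9)) {
    p <- sim_params(seed = 3, bge = bge, noise_cv = 0)
    expect_equal(jelly_mu_mean(p), p$mu_per_h, tolerance = 1e-9)
    expect_equal(jelly_bge_mean(p), 100 * bge, tolerance = 1e-9)
  }
})

test_that("PSM generator is calibrated to the printed pool trajectory", {
  tab <- simulate_psm_table(sim_params(seed = 1))
  totals <- vapply(split(tab, tab$timepoint_h), pool_total, numeric(1))
  expect_equal(totals[["0"]], 203.45, tolerance = 1e-9)
  expect_equal(pool_consumed_pct(totals[["0"]], totals[["32"]]), 97.27,
               tolerance = 0.05)
  expect_lt(100 - pool_consumed_pct(totals[["0"]], totals[["84"]]), 0.1)
  ## all-equal rates: pool ratio is exactly exp(-lambda t)
  prot <- default_protein_table()
  prot$decay_per_h <- 0.1
  tab2 <- simulate_psm_table(sim_params(seed = 1), prot,
                             timepoints_h = c(0, 10))
  tot2 <- vapply(split(tab2, tab2$timepoint_h), pool_total, numeric(1))
  expect_equal(tot2[["10"]] / tot2[["0"]], exp(-1), tolerance = 1e-12)
})

test_that("read-count generator recovers the programmed community profile", {
  profile <- c(Alteromonas = 0.43, Pseudoalteromonas = 0.39, Vibrio = 0.07,
               Others = 0.11)
  fc <- simulate_read_counts(profile, total_reads = 1e6, seed = 4)
  rel <- mag_relative_abundance(setNames(rpm(fc)$rpm, fc$feature_id))
  ## within 3 sigma of the multinomial sampling error
  for (m in names(profile)) {
    se <- sqrt(profile[[m]] * (1 - profile[[m]]) / 1e6) * 100
    expect_lt(abs(rel[[m]] - 100 * profile[[m]]), 3 * se + 1e-9)
  }
  ## single MAG takes everything; unequal lengths are compensated
  one <- simulate_read_counts(c(only = 1), total_reads = 100, seed = 1)
  expect_equal(rpm(one)$rpm, 1e6)
  uneq <- simulate_read_counts(c(a = 0.5, b = 0.5), total_reads = 2e6,
                               lengths = c(1e6, 4e6), seed = 9)
  relu <- mag_relative_abundance(setNames(rpm(uneq)$rpm, uneq$feature_id))
  expect_equal(unname(relu), c(50, 50), tolerance = 1)
  expect_error(simulate_read_counts(c(a = 1), total_reads = 0), "> 0")
})
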