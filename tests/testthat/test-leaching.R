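test_that("release_rate normalises slopes per mg dry mass per day", {
  setup <- leaching_setup(dm_mass_mg = 250, volume_L = 1)
  ## linear rise 0 -> 110 umol/L over 24 h: both methods give 0.44 exactly
  ser <- linear_series(c(0, 0.5, 1, 2, 6, 8, 12, 24), a = 0, b = 110 / 24)
  for (m in c("ols", "endpoint")) {
    expect_equal(release_rate(ser, setup, method = m)$rate, 0.44,
                 tolerance = 1e-12)
  }
  ## flat series -> 0
  flat <- linear_series(c(0, 6, 12, 24), a = 50, b = 0)
  expect_equal(release_rate(flat, setup)$rate, 0)
  ## grid refinement leaves the rate unchanged on noiseless linear data
  fine <- linear_series(seq(0, 24, by = 0.5), a = 0, b = 110 / 24)
  expect_equal(release_rate(fine, setup)$rate, 0.44, tolerance = 1e-12)
  ## replicate averaging: rates 0.4 and 0.48 -> mean 0.44, sd 0.0566
  two <- rbind(
    linear_series(c(0, 12, 24), 0, 0.4 * 250 / 24, replicate = "F1"),
    linear_series(c(0, 12, 24), 0, 0.48 * 250 / 24, replicate = "F2"))
  rr <- release_rate(two, setup)
  expect_equal(rr$rate, 0.44)
  expect_equal(rr$sd, sd(c(0.4, 0.48)))
  expect_equal(rr$n_replicates, 2L)
  ## degenerate input
  expect_error(release_rate(linear_series(3, 1, 0), setup), ">= 2 timepoints")
  ## negative slope is flagged, not clamped
  down <- linear_series(c(0, 12, 24), a = 50, b = -1)
  expect_true(release_rate(down, setup)$negative)
  expect_lt(release_rate(down, setup)$rate, 0)
})

test_that("saturating series are fitted on the rising limb (prefix R^2)", {
  setup <- leaching_setup()
  k <- 0.005 # slow leaching: nearly linear, initial slope k * plateau
  grid <- c(0, 0.5, 1, 2, 6, 8, 12, 24)
  ser <- ts_record(grid, 110 * (1 - exp(-k * grid)), "DOC")
  got <- release_rate(ser, setup, method = "ols")$rate
  want <- k * 110 * 24 * setup$volume_L / setup$dm_mass_mg
  expect_equal(got, want, tolerance = 0.01)
})

test_that("toc_rate adds rates and combines SDs in quadrature", {
  toc <- toc_rate(as_release_rate("POC", 0.42, 0.07),
                  as_release_rate("DOC", 0.44, 0.03))
  expect_equal(toc$rate, 0.86)
  expect_equal(toc$sd, sqrt(0.07^2 + 0.03^2))
  expect_equal(toc_rate(as_release_rate("POC", 0),
                        as_release_rate("DOC", 0.37))$rate, 0.37)
  expect_error(toc_rate(as_release_rate("DOC", 1), as_release_rate("DOC", 1)),
               "POC")
})

test_that("toc_percent_of_dm and lmw_fraction do the percentage arithmetic", {
  expect_equal(toc_percent_of_dm(0.86), 1.033, tolerance = 1e-3)
  expect_equal(toc_percent_of_dm(0), 0)
  expect_equal(toc_percent_of_dm(8.33), 8.33 * 12.011 / 10, tolerance = 1e-12)
  expect_equal(lmw_fraction(6, 100), 6)
  expect_equal(lmw_fraction(9, 100), 9)
  expect_equal(lmw_fraction(0, 42), 0)
  expect_error(lmw_fraction(1, 0), "> 0")
})

test_that("din_partition sums species and computes shares", {
  din <- din_partition(0.0069, 0.0034, 0.00058)
  expect_equal(din$din_total, 0.01088)
  expect_equal(round(din$din_total, 2), 0.01)
  expect_equal(din$shares_pct[["NH4"]], 100 * 0.0069 / 0.01088,
               tolerance = 1e-12)
  expect_equal(sum(din$shares_pct), 100)
  expect_equal(din_partition(0.5, 0, 0)$shares_pct[["NH4"]], 100)
  expect_error(din_partition(0, 0, 0), "undefined")
})

test_that("predict_enrichment and bloom_load are the scenario arithmetic", {
  expect_equal(predict_enrichment(as_release_rate("DOC", 0.44), 100), 44)
  expect_equal(predict_enrichment(as_release_rate("TDN", 0.13), 100), 13)
  expect_equal(predict_enrichment(0.44, 0), 0)
  b <- bloom_load(10, 10, 0.02)
  expect_equal(b$dm_g_per_m3, 100)
  expect_equal(b$c_g_per_m3, 2)
  expect_equal(bloom_load(0, 10)$dm_g_per_m3, 0)
  b2 <- bloom_load(5, 11, 0.02)
  expect_equal(b2$dm_g_per_m3, 55)
  expect_equal(b2$c_g_per_m3, 1.1)
})

test_that("release_rate_table enforces N-pool consistency", {
  setup <- leaching_setup()
  mk <- function(analyte, rate) {
    linear_series(c(0, 12, 24), 0, rate * setup$dm_mass_mg / 24,
                  analyte = analyte)
  }
  ok <- rbind(mk("TDN", 0.13), mk("DIN", 0.01088), mk("DON", 0.13 - 0.01088),
              mk("NH4", 0.0069), mk("NO3", 0.0034), mk("NO2", 0.00058))
  tab <- release_rate_table(ok, setup)
  expect_setequal(tab$analyte, c("TDN", "DIN", "DON", "NH4", "NO3", "NO2"))
  expect_equal(tab$rate_ug_per_mg_per_d[tab$analyte == "TDN"],
               0.13 * 14.007, tolerance = 1e-9)
  bad <- rbind(mk("TDN", 0.13), mk("DIN", 0.05), mk("DON", 0.12))
  expect_warning(release_rate_table(bad, setup), "DON != TDN - DIN")
})
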