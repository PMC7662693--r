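test_that("detect_exponential_window recovers an exact exponential", {
  win <- detect_exponential_window(exp_cells(c(0, 6, 12, 24)))
  expect_equal(win$t_start_h, 0)
  expect_equal(win$t_end_h, 24)
  expect_equal(win$mu_per_h, 0.1, tolerance = 1e-12)
  expect_equal(win$r_squared, 1, tolerance = 1e-12)
  expect_equal(win$n_points, 4L)
})

test_that("window detection matches a brute-force search on piecewise data", {
  ## growth to 32 h then a plateau with a small dip
  t <- c(0, 6, 12, 24, 32, 46, 56)
  y <- c(1e5 * exp(0.09 * pmin(t, 32)))[seq_along(t)]
  y[t > 32] <- y[t == 32] * c(1.001, 0.97)
  ser <- ts_record(t, y, "cells", unit = "cells/mL")
  win <- detect_exponential_window(ser)
  expect_lte(win$t_end_h, max(t[which.max(y)]))
  ## brute force: all contiguous windows of >= 3 points ending at the max
  imax <- which.max(y)
  brute <- expand.grid(i = 1:(imax - 2), j = 3:imax)
  brute <- brute[brute$j - brute$i >= 2, ]
  r2 <- mapply(function(i, j) {
    f <- lm(log(y[i:j]) ~ t[i:j]); 1 - sum(residuals(f)^2) /
      sum((log(y[i:j]) - mean(log(y[i:j])))^2)
  }, brute$i, brute$j)
  expect_equal(win$r_squared, max(r2), tolerance = 1e-9)
})

test_that("degenerate cell series are rejected", {
  flat <- ts_record(c(0, 6, 12, 24), rep(1e5, 4), "cells", unit = "cells/mL")
  expect_error(detect_exponential_window(flat), "no growth")
  down <- ts_record(c(0, 6, 12, 24), 1e5 * exp(-0.05 * c(0, 6, 12, 24)),
                    "cells", unit = "cells/mL")
  expect_error(detect_exponential_window(down), "no growth")
  expect_error(detect_exponential_window(exp_cells(c(0, 6, 12))),
               ">= 4 timepoints")
})

test_that("growth_rate converts to per day", {
  expect_equal(growth_rate(growth_window(0, 24, mu_per_h = 0.09))$mu_per_d,
               2.16)
  expect_equal(growth_rate(growth_window(0, 24, mu_per_h = 0))$mu_per_d, 0)
  ## doubling every hour
  win <- detect_exponential_window(
    ts_record(0:3, 2^(0:3), "cells", unit = "cells/mL"))
  expect_equal(win$mu_per_h, log(2), tolerance = 1e-12)
})

test_that("carbon_budget closes exactly on the budget identity", {
  ## flask with programmed BGE 65%, mu 0.09, zero noise
  t <- c(0, 6, 12, 24, 32)
  n0 <- 5.7e5; mu <- 0.09; bge <- 0.65; fg <- 19.8
  cells <- n0 * exp(mu * t)
  doc0 <- 114
  doc <- doc0 - (cells - n0) * 1000 * fg * 1e-9 / (bge * 12.011)
  win <- growth_window(0, 32, n_points = 5, mu_per_h = mu, r_squared = 1)
  for (m in c("ols", "endpoint")) {
    cb <- carbon_budget(ts_record(t, doc, "DOC"),
                        ts_record(t, cells, "cells", unit = "cells/mL"),
                        win, method = m)
    expect_equal(cb$bge_pct, 65, tolerance = 1e-9)
    expect_equal(cb$br_ugC_L_h / cb$bcd_ugC_L_h, 0.35, tolerance = 1e-9)
    expect_equal(cb$br_ugC_L_h + cb$bp_ugC_L_h, cb$bcd_ugC_L_h,
                 tolerance = 1e-12)
  }
  ## BB is the biomass carbon at the window end
  cb <- carbon_budget(ts_record(t, doc, "DOC"),
                      ts_record(t, cells, "cells", unit = "cells/mL"), win)
  expect_equal(cb$bb_ugC_L, cells[5] * 1000 * fg * 1e-9)
  ## constant DOC with growing cells: no net consumption, BGE undefined
  cb0 <- carbon_budget(ts_record(t, rep(doc0, 5), "DOC"),
                       ts_record(t, cells, "cells", unit = "cells/mL"), win)
  expect_true("no_net_consumption" %in% cb0$flags)
  expect_true(is.na(cb0$bge_pct))
  ## window not covered by the data
  expect_error(carbon_budget(ts_record(c(40, 50), c(1, 1), "DOC"),
                             ts_record(t, cells, "cells", unit = "cells/mL"),
                             win), "cover")
})

test_that("aggregate_budgets averages per-replicate values (BGE order matters)", {
  ## BGEs 38 and 92 from very different BCD scales: mean must be 65,
  ## not 100 * mean(BP) / mean(BCD)
  b1 <- fake_budget(bcd = 10, bp = 3.8)   # BGE 38
  b2 <- fake_budget(bcd = 100, bp = 92)   # BGE 92
  agg <- aggregate_budgets(list(b1, b2))
  bge_row <- agg[agg$quantity == "bge_pct", ]
  expect_equal(bge_row$mean, 65)
  expect_false(isTRUE(all.equal(bge_row$mean,
                                100 * mean(c(3.8, 92)) / mean(c(10, 100)))))
  ## identical replicates -> SD 0; permutation invariance
  same <- aggregate_budgets(list(b1, b1, b1))
  expect_equal(same[same$quantity == "bcd_ugC_L_h", "sd"], 0)
  perm <- aggregate_budgets(list(b2, b1))
  expect_equal(perm$mean, agg$mean)
  expect_error(aggregate_budgets(list(b1)), ">= 2 replicates")
  ## control comparison wires in the pooled t-test
  ctl <- list(fake_budget(1, 0.1, mu = 0.01), fake_budget(2, 0.2, mu = 0.02),
              fake_budget(3, 0.3, mu = 0.03))
  trt <- list(fake_budget(10, 5, mu = 0.08), fake_budget(12, 6, mu = 0.09),
              fake_budget(14, 7, mu = 0.10))
  ## the fake arms have zero within-arm BGE variance: the p = 0 convention
  ## fires for that quantity, by design
  expect_warning(agg2 <- aggregate_budgets(trt, ctl), "convention")
  p_bcd <- agg2[agg2$quantity == "bcd_ugC_L_h", "p_value"]
  expect_equal(p_bcd, two_sample_t_test(c(10, 12, 14), c(1, 2, 3))$p)
})

test_that("two_sample_t_test is the pooled-variance Student test", {
  tt <- two_sample_t_test(c(10, 12, 14), c(1, 2, 3))
  expect_equal(tt$t, 7.745967, tolerance = 1e-6)
  expect_equal(tt$df, 4)
  ref <- t.test(c(10, 12, 14), c(1, 2, 3), var.equal = TRUE)
  expect_equal(tt$p, ref$p.value)
  expect_equal(two_sample_t_test(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_lt(two_sample_t_test(c(1, 2, 3), c(101, 102, 103))$p, 1e-6)
  ## zero-variance conventions
  expect_equal(two_sample_t_test(c(5, 5), c(5, 5))$p, 1)
  expect_warning(p0 <- two_sample_t_test(c(5, 5), c(6, 6))$p, "convention")
  expect_equal(p0, 0)
})

test_that("t-test p agrees with exact permutation p on small arms", {
  perm_p <- function(a, b) {
    pool <- c(a, b); na <- length(a)
    idx <- combn(length(pool), na)
    t_obs <- abs(two_sample_t_test(a, b)$t)
    t_all <- apply(idx, 2, function(i) {
      abs(two_sample_t_test(pool[i], pool[-i])$t)
    })
    mean(t_all >= t_obs - 1e-12)
  }
  set.seed(11)
  for (shift in c(0, 1.5)) {
    a <- rnorm(6); b <- rnorm(6) + shift
    expect_lt(abs(two_sample_t_test(a, b)$p - perm_p(a, b)), 0.12)
  }
})
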