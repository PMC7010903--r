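make_cum <- function(A_med, A_mem, A_int, A0 = 1e6) {
  iv <- data.frame(interval = "day1", T1_h = 4, T2_h = 24,
                   A_medium = A_med, A_membrane = A_mem,
                   A_internalized = A_int, stringsAsFactors = FALSE)
  structure(list(intervals = iv, A0_Bq = A0, lambda_p = lu177_lambda_p()),
            class = "cumulated_activities")
}

test_that("colony schedule follows round(2^(24 d / Td)) with day 1 isolated", {
  expect_equal(colony_schedule(24, 6), c(1, 4, 8, 16, 32, 64))
  expect_equal(colony_schedule(1e9, 6), rep(1L, 6))
  expect_equal(colony_schedule(36, 6)[3], 4L)
  expect_error(colony_schedule(0), "doubling time")
})

test_that("single-term dose reduces to the S value and the sum is exact", {
  stab <- ref_monolayer_s()
  d <- compute_absorbed_dose(make_cum(1, 0, 0), stab, "cytoplasm")
  expect_equal(d$total_Gy, stab$medium[stab$interval == "day1"])
  d2 <- compute_absorbed_dose(make_cum(2, 3, 5), stab, "cytoplasm")
  s <- stab[stab$interval == "day1", ]
  expect_equal(d2$total_Gy, 2 * s$medium + 3 * s$membrane + 5 * s$cytoplasm)
  expect_equal(d2$per_interval$dose_total,
               with(d2$per_interval, dose_membrane + dose_internalized + dose_medium))
})

test_that("dose is linear in the added activity at fixed fractions", {
  cfg <- synthetic_config()
  cfg$cv_fractions <- 0; cfg$cv_counts <- 0; cfg$cv_activity <- 0
  ds <- generate_uptake_dataset(cfg, seed = 3)
  stab <- ref_monolayer_s()
  cum1 <- pipeline_cumulated(ds, 1)
  cum2 <- cum1
  cum2$intervals[, c("A_medium", "A_membrane", "A_internalized")] <-
    2 * cum2$intervals[, c("A_medium", "A_membrane", "A_internalized")]
  d1 <- compute_absorbed_dose(cum1, stab, "cytoplasm")
  d2 <- compute_absorbed_dose(cum2, stab, "cytoplasm")
  expect_equal(d2$total_Gy, 2 * d1$total_Gy)
})

test_that("switching the internalized source from cytoplasm to Golgi scales by the S ratio", {
  stab <- ref_monolayer_s()
  cum <- make_cum(0, 0, 1)
  d_cy <- compute_absorbed_dose(cum, stab, "cytoplasm")
  d_g <- compute_absorbed_dose(cum, stab, "golgi")
  expect_equal(d_g$total_Gy / d_cy$total_Gy, 9.35e-5 / 5.84e-5,
               tolerance = 1e-9)
})

test_that("missing S values are reported by interval", {
  stab <- ref_monolayer_s()
  cum <- make_cum(0, 1, 1)
  cum$intervals$interval <- "day9"
  expect_error(compute_absorbed_dose(cum, stab, "cytoplasm"), "day9")
})

test_that("scenario comparison reproduces the published dose ratios", {
  ratios <- scenario_compare(ref_cumulative_doses())
  sp_pm <- ratios[ratios$scenario_a == "sphere" & ratios$scenario_b == "PM_Cy", ]
  sp_pm <- sp_pm[order(sp_pm$activity), ]
  expect_equal(sp_pm$ratio, c(3.00, 3.086, 3.011, 2.859, 2.765),
               tolerance = 1e-3)
  g_cy <- ratios[ratios$scenario_a == "PM_G" & ratios$scenario_b == "PM_Cy" &
                   ratios$activity == 0.5, ]
  expect_equal(g_cy$ratio, 1.36 / 0.92, tolerance = 1e-9)
})

test_that("identical scenarios compare at ratio 1; provenance mismatches error", {
  stab <- ref_monolayer_s()
  d1 <- compute_absorbed_dose(make_cum(1, 2, 3), stab, "cytoplasm")
  d2 <- compute_absorbed_dose(make_cum(1, 2, 3), stab, "cytoplasm")
  cmp <- scenario_compare(list(a = d1, b = d2))
  expect_true(all(cmp$ratio == 1))
  d3 <- compute_absorbed_dose(make_cum(1, 2, 3, A0 = 2e6), stab, "cytoplasm")
  expect_error(scenario_compare(list(a = d1, b = d3)), "provenance")
})

test_that("uncertainty propagation adds relative SDs in quadrature", {
  expect_equal(propagate_uncertainty(0.07), 0.07)
  expect_equal(propagate_uncertainty(c(0.03, 0.04)), 0.05)
  expect_equal(propagate_uncertainty(rep(0, 5)), 0)
  expect_error(propagate_uncertainty(-0.1), ">= 0")
})

test_that("engine-built monolayer S tables have isolated day-1 cells and additive structure", {
  tab <- monolayer_s_table(cell_avg, Td_h = 24, days = 2, n_histories = 3000,
                           seed = 21, spectrum = spec_lu, material = mat_water)
  expect_equal(tab$interval, c("uptake", "day1", "day2"))
  expect_equal(tab$cluster_size[-1], c(1L, 4L))
  s_self <- self_s_value(cell_avg, "cytoplasm", 3000, seed = 21,
                         spectrum = spec_lu, material = mat_water)
  # day 1 = isolated cells: monolayer value is the pure self S value
  expect_equal(tab$cytoplasm[tab$interval == "day1"], s_self$value)
  expect_gt(tab$cytoplasm[tab$interval == "day2"], tab$cytoplasm[2])
  expect_true(is.na(tab$medium[3]) && !is.na(tab$medium[2]))
})

test_that("end-to-end noiseless dose matches the generator's analytic truth", {
  cfg <- synthetic_config()
  cfg$cv_fractions <- 0; cfg$cv_counts <- 0; cfg$cv_activity <- 0
  ds <- generate_uptake_dataset(cfg, seed = 4)
  stab <- ref_monolayer_s()
  for (a in c(0.25, 2.5)) {
    d_est <- compute_absorbed_dose(pipeline_cumulated(ds, a), stab, "cytoplasm")
    d_tru <- compute_absorbed_dose(ds$truth$cumulated[[paste0("a", a)]],
                                   stab, "cytoplasm")
    expect_equal(d_est$total_Gy, d_tru$total_Gy, tolerance = 5e-3)
  }
})
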