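noiseless_cfg <- function(...) {
  cfg <- synthetic_config(...)
  cfg$cv_fractions <- 0; cfg$cv_counts <- 0; cfg$cv_activity <- 0
  cfg
}

test_that("configuration guards its noise ranges and round-trips through YAML-free lists", {
  expect_error(synthetic_config(cv_fractions = 0.5), "5-33")
  expect_error(synthetic_config(cv_counts = 0.3), "11-18")
  expect_error(synthetic_config(cv_activity = 0.2), "1-3")
  cfg <- synthetic_config()
  expect_identical(cfg, do.call(synthetic_config,
                                cfg[setdiff(names(cfg), "a_ref")]))
})

test_that("zero-CV datasets equal the analytic truth exactly", {
  ds <- generate_uptake_dataset(noiseless_cfg(), seed = 5)
  one <- ds$uptake[ds$uptake$experiment == 1 & ds$uptake$replicate == 1 &
                     ds$uptake$added_activity == 2.5 &
                     ds$uptake$compartment == "internalized", ]
  cfg <- noiseless_cfg()
  tru <- celldose:::.uptake_truth(cfg, one$time_h, 2.5)
  expect_equal(one$fraction, tru$internalized)
  # compartment conservation before noise
  tot <- aggregate(fraction ~ time_h, ds$uptake[ds$uptake$experiment == 1 &
    ds$uptake$replicate == 1 & ds$uptake$added_activity == 1, ], sum)
  expect_equal(tot$fraction, rep(1, nrow(tot)))
})

test_that("datasets are byte-identical for a fixed seed", {
  a <- generate_uptake_dataset(synthetic_config(), seed = 9)
  b <- generate_uptake_dataset(synthetic_config(), seed = 9)
  expect_identical(a, b)
  c_ <- generate_uptake_dataset(synthetic_config(), seed = 10)
  expect_false(identical(a$uptake$fraction, c_$uptake$fraction))
})

test_that("empirical noise CV matches the configured CV", {
  cfg <- synthetic_config(activities = 2.5, cv_fractions = 0.2)
  vals <- unlist(lapply(1:150, function(s) {
    ds <- generate_uptake_dataset(cfg, seed = 1000 + s)
    ds$uptake$fraction[ds$uptake$compartment == "internalized" &
                         ds$uptake$time_h == 4]
  }))
  cv <- sd(vals) / mean(vals)
  expect_lt(abs(cv / 0.2 - 1), 0.2)
})

test_that("survival generator: closed form, zero dose, and binomial realisation", {
  ds <- generate_survival_dataset(0.33, c(0, 1), replicates = 1,
                                  noise_cv = 0, seed = 1)
  expect_equal(ds$sf[ds$dose_Gy == 0], 1)
  expect_equal(ds$sf[ds$dose_Gy == 1], exp(-0.33), tolerance = 1e-12)

  db <- generate_survival_dataset(0.33, 1, replicates = 1000, binomial = TRUE,
                                  seeded = 300, plating_efficiency = 0.5,
                                  seed = 2)
  p <- exp(-0.33) * 0.5
  se <- sqrt(p * (1 - p) / (300 * 1000)) / 0.5
  expect_lt(abs(mean(db$sf) - exp(-0.33)), 3 * se)
})

test_that("generated mesh cells hit target volumes and pass validity checks", {
  cell <- generate_mesh_cell(3603, 1334, 60, seed = 12)
  expect_equal(cell$volumes$cell, 3603, tolerance = 0.01)
  expect_equal(cell$volumes$nucleus, 1334, tolerance = 0.01)
  expect_equal(cell$volumes$golgi, 60, tolerance = 0.01)
  for (m in cell$meshes) expect_true(mesh_is_watertight(m))

  # amplitude 0: vertices lie exactly on an ellipsoid
  e0 <- generate_mesh_cell(3546, 1061, 55, amplitude = 0, seed = 13)
  v <- e0$meshes$cytoplasm$vertices
  semi <- apply(v, 2, function(u) diff(range(u))) / 2
  resid <- rowSums(sweep(v, 2, semi, "/")^2) - 1
  expect_lt(max(abs(resid)), 1e-9)

  expect_identical(generate_mesh_cell(3603, 1334, 60, seed = 12)$meshes,
                   cell$meshes)
})

test_that("mesh OBJ files round-trip through the loader", {
  dir <- tempfile()
  cell <- generate_mesh_cell(3000, 900, 50, seed = 14, dir = dir)
  files <- attr(cell, "files")
  expect_true(all(file.exists(files)))
  cell2 <- load_mesh_cell(files[1], files[2], files[3])
  expect_equal(cell2$volumes$cell, cell$volumes$cell, tolerance = 1e-6)
})

test_that("closed loop: noiseless pipeline returns the generator's alpha", {
  cfg <- noiseless_cfg()
  ds <- generate_uptake_dataset(cfg, seed = 6)
  stab <- ref_monolayer_s()
  d_est <- vapply(cfg$activities, function(a)
    compute_absorbed_dose(pipeline_cumulated(ds, a), stab, "cytoplasm")$total_Gy, 0)
  d_tru <- vapply(cfg$activities, function(a)
    compute_absorbed_dose(ds$truth$cumulated[[paste0("a", a)]], stab,
                          "cytoplasm")$total_Gy, 0)
  sf <- exp(-cfg$alpha_true * d_tru)
  fit <- fit_dose_response(d_est, sf, "linear")
  expect_lt(abs(fit$alpha / cfg$alpha_true - 1), 0.005)
})

test_that("closed loop at experiment-scale noise recovers alpha within 10%", {
  stab <- ref_monolayer_s()
  cfg0 <- synthetic_config()
  d_tru <- vapply(cfg0$activities, function(a) {
    ds0 <- generate_uptake_dataset(noiseless_cfg(), seed = 1)
    compute_absorbed_dose(ds0$truth$cumulated[[paste0("a", a)]], stab,
                          "cytoplasm")$total_Gy
  }, 0)
  est <- vapply(1:100, function(s) {
    ds <- generate_uptake_dataset(cfg0, seed = 2000 + s)
    d_est <- vapply(cfg0$activities, function(a)
      compute_absorbed_dose(pipeline_cumulated(ds, a), stab,
                            "cytoplasm")$total_Gy, 0)
    sv <- generate_survival_dataset(cfg0$alpha_true, d_tru, replicates = 3,
                                    noise_cv = 0.15, seed = 3000 + s)
    sf <- aggregate(sf ~ dose_Gy, sv, mean)
    sf <- sf[match(d_tru, sf$dose_Gy), ]
    fit_dose_response(d_est, sf$sf, "linear")$alpha
  }, 0)
  expect_lt(abs(median(est) / cfg0$alpha_true - 1), 0.1)
})
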