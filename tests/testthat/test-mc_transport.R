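test_that("ray deposits: misses, full stops, and the stopping-power integral", {
  cell <- cell_avg
  # ray far above the cell never crosses the nucleus
  expect_equal(deposit_along_ray(c(0, 0, 50), c(1, 0, 0), 100, cell, mat_water), 0)

  # low-energy electron entering the nucleus stops inside: deposits all
  # residual energy at entry
  zc <- cell$nucleus$centre[3]
  dep <- deposit_along_ray(c(-15, 0, zc), c(1, 0, 0), 20, cell, mat_water)
  r20 <- csda_range(20, mat_water)
  t_entry <- 15 - cell$nucleus$semi[1]
  expect_lt(r20 - t_entry, 2 * cell$nucleus$semi[1])  # really stops inside
  expect_equal(dep, residual_energy(r20 - t_entry, mat_water), tolerance = 1e-9)

  # partial traversal equals fine-step numerical integration of S(E) along
  # the chord
  o <- c(0, -30, zc); d <- c(0, 1, 0); E <- 150
  dep <- deposit_along_ray(o, d, E, cell, mat_water)
  tt <- seq(0, csda_range(E, mat_water), length.out = 50001)
  mid <- (tt[-1] + tt[-length(tt)]) / 2
  pts <- cbind(o[1] + mid * d[1], o[2] + mid * d[2], o[3] + mid * d[3])
  inside <- in_compartment(cell, pts, "nucleus")
  eres <- residual_energy(pmax(csda_range(E, mat_water) - tt, 0), mat_water)
  dep_num <- -sum(diff(eres) * inside)
  expect_equal(dep, dep_num, tolerance = 1e-3)
})

test_that("per-history deposit never exceeds the emitted energy", {
  set.seed(10)
  n <- 2000
  E <- sample_electron(spec_lu, n)
  org <- sample_point_in_compartment(cell_avg, "cytoplasm", n)
  dirs <- matrix(rnorm(3 * n), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  dep <- deposit_along_ray(org, dirs, E, cell_avg, mat_water)
  expect_true(all(dep <= E + 1e-9))
  expect_true(all(dep >= 0))
})

test_that("full-absorption limit: S(N<-N) approaches Delta/m for a huge nucleus", {
  big <- make_sphere_cell(1.1e7, 1e7)
  s <- self_s_value(big, "nucleus", 1e6, seed = 5, spectrum = spec_lu,
                    material = mat_water)
  expected <- spec_lu$delta_keV * 1.602176634e-16 / (big$volumes$nucleus * 1e-15)
  expect_lt(abs(s$value - expected), 2 * s$se + 2e-4 * expected)
})

test_that("S values are seed-reproducible and scale like 1/sqrt(n)", {
  a <- self_s_value(cell_avg, "cytoplasm", 5000, seed = 3, spectrum = spec_lu,
                    material = mat_water)
  b <- self_s_value(cell_avg, "cytoplasm", 5000, seed = 3, spectrum = spec_lu,
                    material = mat_water)
  expect_identical(a$value, b$value)

  big <- self_s_value(cell_avg, "cytoplasm", 4 * 5000, seed = 4,
                      spectrum = spec_lu, material = mat_water)
  expect_equal(big$se / a$se, 0.5, tolerance = 0.2)
})

test_that("cross-dose is additive over neighbours and symmetric in the first ring", {
  lay <- layout_monolayer(cell_avg, gap = 0,
                          cutoff_um = cell_avg$footprint_diameter * 1.1)
  expect_equal(nrow(lay$positions), 6)
  cs <- cross_s_value(cell_avg, lay, "cytoplasm", 6e4, seed = 6,
                      spectrum = spec_lu, material = mat_water)
  expect_identical(cs$value, sum(cs$per_neighbour$value))
  dev <- abs(cs$per_neighbour$value - mean(cs$per_neighbour$value))
  expect_true(all(dev < 4 * cs$per_neighbour$se))

  # empty layout (isolated cell): cross-dose is exactly zero
  c0 <- cross_s_value(cell_avg, layout_cluster(cell_avg, 1), "cytoplasm",
                      1e4, seed = 7, spectrum = spec_lu, material = mat_water)
  expect_identical(c0$value, 0)
})

test_that("total cross-dose does not depend significantly on the source location", {
  lay <- layout_monolayer(cell_avg, gap = 0, cutoff_um = 150)
  c_cy <- cross_s_value(cell_avg, lay, "cytoplasm", 2e5, seed = 8,
                        spectrum = spec_lu, material = mat_water)
  c_cs <- cross_s_value(cell_avg, lay, "membrane", 2e5, seed = 9,
                        spectrum = spec_lu, material = mat_water)
  expect_lt(abs(c_cy$value - c_cs$value),
            3 * sqrt(c_cy$se^2 + c_cs$se^2) + 0.1 * c_cy$value)
})

test_that("medium source: orders of magnitude below self-dose and CPE limit", {
  sm <- medium_s_value(cell_avg, build_well(), 1e5, seed = 10,
                       spectrum = spec_lu, material = mat_water)
  scy <- self_s_value(cell_avg, "cytoplasm", 3e4, seed = 11,
                      spectrum = spec_lu, material = mat_water)
  orders <- log10(scy$value / sm$value)
  expect_gt(orders, 5.5)
  expect_lt(orders, 8.5)

  # point deep inside an effectively infinite medium: equilibrium dose rate
  # Delta * concentration / rho
  wb <- build_well(volume_ml = 8)
  s_cpe <- medium_s_value(cell_avg, wb, 2e5, seed = 12, spectrum = spec_lu,
                          material = mat_water, cell_base_z = wb$height_um / 2)
  cpe <- spec_lu$delta_keV * 1.602176634e-16 / (wb$volume_um3 * 1e-15)
  expect_equal(s_cpe$value, cpe, tolerance = 0.05)
})

test_that("self S values decrease with cell volume on an exponential trend", {
  sw <- parameter_sweep("volume", c(1900, 2800, 3500, 4500, 5500),
                        n_histories = 2e4, seed = 13, spectrum = spec_lu,
                        material = mat_water)
  expect_true(all(diff(sw$s_self) < 0))
  expect_gt(fit_exponential_trend(sw$value, sw$s_self)$r_squared, 0.9)
})

test_that("Golgi-source dose drops when the nucleus shifts away", {
  s0 <- self_s_value(tc_cell(), "golgi", 3e4, seed = 14, spectrum = spec_lu,
                     material = mat_water)$value
  s3 <- self_s_value(tc_cell(nucleus_offset = c(-3, 0)), "golgi", 3e4,
                     seed = 15, spectrum = spec_lu, material = mat_water)$value
  red <- 100 * (1 - s3 / s0)
  expect_gt(red, 5)    # printed interval 15-36% with +/-10 points slack
  expect_lt(red, 46)
})

test_that("mesh-cell transport gives S values consistent with the ellipsoid engine", {
  # same flat-ellipsoid morphology built as an exact mesh vs the analytic
  # nucleus chord solver: a dual-route check of the mesh kernel
  mcell <- generate_mesh_cell(3482, 1045, 55, amplitude = 0, seed = 16)
  s_mesh <- self_s_value(mcell, "nucleus", 8000, seed = 17,
                         spectrum = spec_lu, material = mat_water)
  semi <- apply(mcell$meshes$nucleus$vertices, 2, function(u) diff(range(u))) / 2
  ctr <- colMeans(mcell$meshes$nucleus$vertices)
  ecell <- list(shape = "ellipsoid",
                nucleus = list(type = "ellipsoid", centre = ctr, semi = semi),
                golgi = NULL,
                volumes = list(nucleus = 4 / 3 * pi * prod(semi)))
  class(ecell) <- "cell_model"
  s_ell <- self_s_value(ecell, "nucleus", 8000, seed = 18,
                        spectrum = spec_lu, material = mat_water)
  expect_equal(s_mesh$value, s_ell$value,
               tolerance = 4 * (s_mesh$se + s_ell$se) / s_ell$value + 0.05)
})
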