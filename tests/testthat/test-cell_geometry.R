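test_that("sphere cell volumes follow the closed form and protrusion errors fire", {
  cell <- make_sphere_cell(9, 6)
  expect_equal(cell$volumes$cell, 4 / 3 * pi * 9^3)      # ~3054 um^3
  expect_equal(cell$volumes$nucleus, 4 / 3 * pi * 6^3)   # ~905 um^3
  expect_error(make_sphere_cell(9, 9), "nucleus radius")
  expect_error(make_sphere_cell(9, 6, c(0, 0, 4)), "protrudes")
})

test_that("truncated-cone volumes are closed-form and the family spans the observed ranges", {
  cell <- make_truncated_cone_cell(12, 6, 10, nucleus_a = 5, nucleus_c = 3,
                                   golgi_tube_radius = 0)
  expect_equal(cell$volumes$cell, pi * 10 * (144 + 72 + 36) / 3)  # 2638.94
  expect_equal(cell$volumes$nucleus, 4 / 3 * pi * 25 * 3)

  lo <- tc_cell(1900); hi <- tc_cell(5500)
  expect_equal(lo$volumes$cell, 1900, tolerance = 1e-3)
  expect_equal(hi$volumes$cell, 5500, tolerance = 1e-3)
  expect_true(lo$volumes$nucleus > 560 && lo$volumes$nucleus < 580)
  expect_true(hi$volumes$nucleus > 1640 && hi$volumes$nucleus < 1660)
})

test_that("Golgi half-torus respects the minimum Golgi-nucleus distance", {
  cell <- tc_cell()
  g <- cell$golgi
  set.seed(4)
  # dense samples on both surfaces; brute-force nearest-pair distance
  phi <- runif(3000, -pi / 2, pi / 2); th <- runif(3000, 0, 2 * pi)
  rho <- g$ring_radius + g$tube_radius * cos(th)
  gp <- cbind(rho * sin(phi), rho * cos(phi), g$tube_radius * sin(th))
  gp <- sweep(gp, 2, g$centre, "+")
  u <- matrix(rnorm(3000 * 3), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  np <- sweep(u %*% diag(cell$nucleus$semi), 2, cell$nucleus$centre, "+")
  dmin <- min(vapply(seq_len(nrow(gp)), function(i)
    min(sqrt(colSums((t(np) - gp[i, ])^2))), 0))
  expect_gte(dmin, g$d_gn - 0.05)
})

test_that("containment violations raise geometry errors", {
  expect_error(make_truncated_cone_cell(12, 6, 5, nucleus_a = 5, nucleus_c = 3,
                                        golgi_tube_radius = 0),
               "nucleus")
  expect_error(make_truncated_cone_cell(12, 6, 10, nucleus_a = 11, nucleus_c = 3,
                                        golgi_tube_radius = 0),
               "nucleus")
})

test_that("compartment sampling is contained and uniform", {
  for (comp in c("cytoplasm", "nucleus", "golgi")) {
    pts <- sample_point_in_compartment(cell_avg, comp, 5000, seed = 5)
    expect_true(all(in_compartment(cell_avg, pts, comp)))
  }
  # octant chi-square on a concentric spherical nucleus
  sph <- make_sphere_cell(9, 6)
  pts <- sample_point_in_compartment(sph, "nucleus", 16000, seed = 6)
  rel <- sweep(pts, 2, sph$nucleus$centre)
  oct <- paste(rel[, 1] > 0, rel[, 2] > 0, rel[, 3] > 0)
  p <- chisq.test(table(oct))$p.value
  expect_gt(p, 0.01)
})

test_that("membrane sampling lies on the cell surface", {
  sph <- make_sphere_cell(9, 6)
  pts <- sample_point_in_compartment(sph, "membrane", 2000, seed = 7)
  r <- sqrt(colSums((t(pts) - sph$centre)^2))
  expect_lt(max(abs(r - 9)), 1e-6)

  pts <- sample_point_in_compartment(cell_avg, "membrane", 4000, seed = 8)
  z <- pts[, 3]; rho <- sqrt(pts[, 1]^2 + pts[, 2]^2)
  on_base <- abs(z) < 1e-9 & rho <= cell_avg$base_radius + 1e-6
  on_top <- abs(z - cell_avg$height) < 1e-9 & rho <= cell_avg$top_radius + 1e-6
  r_at_z <- cell_avg$base_radius +
    (cell_avg$top_radius - cell_avg$base_radius) * z / cell_avg$height
  on_side <- abs(rho - r_at_z) < 1e-6
  expect_true(all(on_base | on_top | on_side))
  expect_true(any(on_base) && any(on_top) && any(on_side))
})

test_that("monolayer layouts have hexagonal structure and match brute-force enumeration", {
  sph <- make_sphere_cell(9, 6)  # footprint diameter 18
  lay <- layout_monolayer(sph, gap = 0, cutoff_um = 280)
  d <- sqrt(rowSums(lay$positions^2))
  expect_equal(min(d), 18, tolerance = 1e-9)
  expect_equal(sum(abs(d - 18) < 1e-9), 6)

  lay5 <- layout_monolayer(sph, gap = 5)
  expect_equal(min(sqrt(rowSums(lay5$positions^2))), 6 * 18, tolerance = 1e-9)

  # independent brute-force lattice scan
  pitch <- 18
  ij <- expand.grid(i = -40:40, j = -40:40)
  x <- (ij$i + ij$j / 2) * pitch; y <- ij$j * pitch * sqrt(3) / 2
  n_bf <- sum(x^2 + y^2 <= 280^2) - 1
  expect_equal(nrow(lay$positions), n_bf)

  # symmetry: neighbour enumeration is reciprocal
  key <- paste(round(lay$positions[, 1], 6), round(lay$positions[, 2], 6))
  neg <- paste(round(-lay$positions[, 1], 6), round(-lay$positions[, 2], 6))
  expect_setequal(key, neg)
})

test_that("cluster layouts are compact and sized correctly", {
  expect_equal(nrow(layout_cluster(cell_avg, 1)$positions), 0)
  lay <- layout_cluster(cell_avg, 7)
  expect_equal(nrow(lay$positions), 6)
  d <- sqrt(rowSums(lay$positions^2))
  expect_true(all(abs(d - cell_avg$footprint_diameter) < 1e-9))
})

test_that("well geometry satisfies h = V/(pi r^2) and round-trips", {
  w <- build_well(1, 11.05)
  expect_equal(w$height_mm, 1000 / (pi * 11.05^2))
  expect_equal(w$height_mm, 2.607, tolerance = 1e-3)
  expect_equal(build_well(2, 11.05)$height_mm, 2 * w$height_mm)
  expect_equal(pi * w$radius_mm^2 * w$height_mm / 1000, w$volume_ml,
               tolerance = 1e-3)
})
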