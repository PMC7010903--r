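# Cell geometries with cytoplasm / membrane / nucleus / Golgi compartments,
# monolayer and colony layouts, and the medium-filled well.
#
# Conventions: right-handed coordinates, z up, adherent cells sit on the
# z = 0 plane, all lengths in micrometres. The membrane is the zero-thickness
# outer cell surface (surface source). The cytoplasm compartment is the cell
# interior minus nucleus and Golgi.

#' Spherical cell model
#'
#' Concentric (or eccentric) sphere cell with a spherical nucleus, the
#' classical MIRD-style cellular geometry. The cell rests on the z = 0 plane
#' (centre at z = `R_cell`).
#'
#' @param R_cell,R_nucleus cell and nucleus radii, um; `R_nucleus < R_cell`.
#' @param nucleus_offset length-3 displacement of the nucleus centre from the
#'   cell centre, um.
#' @return object of class `cell_model`.
#' @export
make_sphere_cell <- function(R_cell, R_nucleus, nucleus_offset = c(0, 0, 0)) {
  if (!(R_nucleus > 0 && R_cell > 0)) stopf("radii must be positive")
  if (R_nucleus >= R_cell) stopf("nucleus radius must be < cell radius")
  if (sqrt(sum(nucleus_offset^2)) + R_nucleus >= R_cell)
    stopf("nucleus protrudes from the cell boundary")
  centre <- c(0, 0, R_cell)
  structure(list(
    shape = "sphere",
    R_cell = R_cell, R_nucleus = R_nucleus,
    centre = centre, nucleus_centre = centre + nucleus_offset,
    nucleus = list(type = "ellipsoid", centre = centre + nucleus_offset,
                   semi = rep(R_nucleus, 3)),
    volumes = list(cell = 4 / 3 * pi * R_cell^3,
                   nucleus = 4 / 3 * pi * R_nucleus^3,
                   golgi = 0,
                   cytoplasm = 4 / 3 * pi * (R_cell^3 - R_nucleus^3)),
    footprint_diameter = 2 * R_cell, height = 2 * R_cell),
    class = "cell_model")
}

#' Truncated-cone (CSG) cell model
#'
#' Adherent cell built from analytic primitives: a conical frustum (base
#' radius `base_radius` at z = 0, top radius `top_radius` at z = `height`),
#' an oblate ellipsoidal nucleus (semi-axes `nucleus_a`, `nucleus_a`,
#' `nucleus_c`) resting near the base, and optionally a half circular torus
#' Golgi wrapped around the nucleus equator at minimum surface distance
#' `golgi_d_gn` from the nucleus. `nucleus_offset` (y, z) displaces the
#' nucleus after the Golgi has been placed, emulating nucleus-position
#' shifts at fixed organelle anatomy.
#'
#' @param base_radius,top_radius,height frustum dimensions, um
#'   (`top_radius < base_radius`).
#' @param nucleus_a,nucleus_c nucleus semi-axes (in-plane, vertical), um.
#' @param nucleus_offset length-2 (y, z) nucleus displacement, um.
#' @param nucleus_clearance gap between nucleus bottom and the base plane, um.
#' @param golgi_tube_radius,golgi_d_gn half-torus tube radius and minimum
#'   Golgi-nucleus surface distance, um; `golgi_tube_radius = 0` omits the
#'   Golgi.
#' @return object of class `cell_model`. Volumes are closed-form: frustum
#'   \eqn{\pi h (R_b^2 + R_b R_t + R_t^2)/3}, ellipsoid
#'   \eqn{4\pi a^2 c/3}, half torus \eqn{\pi^2 R_g r_t^2}.
#' @export
make_truncated_cone_cell <- function(base_radius, top_radius, height,
                                     nucleus_a, nucleus_c,
                                     nucleus_offset = c(0, 0),
                                     nucleus_clearance = 0.3,
                                     golgi_tube_radius = 0.8,
                                     golgi_d_gn = 1.0) {
  if (top_radius >= base_radius) stopf("top radius must be < base radius")
  if (min(base_radius, top_radius, height, nucleus_a, nucleus_c) <= 0)
    stopf("all dimensions must be positive")
  zc0 <- nucleus_c + nucleus_clearance
  n_centre0 <- c(0, 0, zc0)                       # pre-shift nucleus centre
  n_centre <- n_centre0 + c(0, nucleus_offset[1], nucleus_offset[2])

  golgi <- NULL
  if (golgi_tube_radius > 0) {
    ring <- nucleus_a + golgi_d_gn + golgi_tube_radius
    golgi <- list(centre = n_centre0, ring_radius = ring,
                  tube_radius = golgi_tube_radius, d_gn = golgi_d_gn)
  }
  vols <- list(
    cell = pi * height * (base_radius^2 + base_radius * top_radius + top_radius^2) / 3,
    nucleus = 4 / 3 * pi * nucleus_a^2 * nucleus_c,
    golgi = if (is.null(golgi)) 0 else pi^2 * golgi$ring_radius * golgi$tube_radius^2)
  vols$cytoplasm <- vols$cell - vols$nucleus - vols$golgi
  cell <- structure(list(
    shape = "truncated_cone",
    base_radius = base_radius, top_radius = top_radius, height = height,
    nucleus = list(type = "ellipsoid", centre = n_centre,
                   semi = c(nucleus_a, nucleus_a, nucleus_c)),
    golgi = golgi,
    volumes = vols,
    footprint_diameter = 2 * base_radius, height_um = height),
    class = "cell_model")
  .validate_cell(cell)
  cell
}

#' Reference truncated-cone cell family
#'
#' The default adherent-cell family used throughout the package, scaled by
#' similarity so that a target cell volume maps every length by
#' \eqn{k = (V/V_0)^{1/3}}. The reference cell (\eqn{V_0 \approx 3482}
#' um^3) follows the spread adherent-cell morphology seen in confocal
#' stacks of U2OS+SST2 monolayers: a wide flat frustum (footprint diameter
#' 40 um, height 4.75 um), a flattened oblate nucleus (semi-axes 10.65,
#' 10.65, 2.2 um) holding 30% of the cell volume, and a half-torus Golgi wrapped
#' around the nucleus equator at 1 um. Volumes 1900-5500 um^3 then span
#' nucleus volumes ~570-1650 um^3, the observed range.
#'
#' @param volume target cell volume, um^3.
#' @param nucleus_offset (y, z) nucleus displacement, um (applied unscaled).
#' @param golgi include the Golgi half-torus?
#' @return a `cell_model`.
#' @export
tc_cell <- function(volume = 3482, nucleus_offset = c(0, 0), golgi = TRUE) {
  k <- (volume / 3481.5)^(1 / 3)
  make_truncated_cone_cell(
    base_radius = 20 * k, top_radius = 10 * k, height = 4.75 * k,
    nucleus_a = 10.65 * k, nucleus_c = 2.2 * k,
    nucleus_offset = nucleus_offset,
    nucleus_clearance = 0.2 * k,
    golgi_tube_radius = if (golgi) 0.7 * k else 0,
    golgi_d_gn = 1.0 * k)
}

#' @export
print.cell_model <- function(x, ...) {
  v <- x$volumes
  cat(sprintf("<cell_model> %s: V_cell = %.0f, V_N = %.0f, V_G = %.1f um^3\n",
              x$shape, v$cell, v$nucleus, v$golgi))
  invisible(x)
}

# frustum radius at height z
.frustum_r <- function(cell, z)
  cell$base_radius + (cell$top_radius - cell$base_radius) * z / cell$height

.in_cell_boundary <- function(cell, pts) {
  switch(cell$shape,
    sphere = colSums((t(pts) - cell$centre)^2) <= cell$R_cell^2,
    truncated_cone = {
      z <- pts[, 3]
      ok <- z >= 0 & z <= cell$height
      r2 <- pts[, 1]^2 + pts[, 2]^2
      ok & r2 <= pmax(.frustum_r(cell, pmin(pmax(z, 0), cell$height)), 0)^2
    },
    mesh = points_in_mesh(pts, cell$meshes$cytoplasm))
}

.in_ellipsoid <- function(pts, centre, semi) {
  q <- sweep(pts, 2, centre)
  (q[, 1] / semi[1])^2 + (q[, 2] / semi[2])^2 + (q[, 3] / semi[3])^2 <= 1
}

.in_nucleus <- function(cell, pts) {
  if (cell$nucleus$type == "ellipsoid")
    .in_ellipsoid(pts, cell$nucleus$centre, cell$nucleus$semi)
  else points_in_mesh(pts, cell$meshes$nucleus)
}

.in_golgi <- function(cell, pts) {
  if (is.null(cell$golgi)) return(rep(FALSE, nrow(pts)))
  if (!is.null(cell$meshes$golgi)) return(points_in_mesh(pts, cell$meshes$golgi))
  g <- cell$golgi
  q <- sweep(pts, 2, g$centre)
  rho <- sqrt(q[, 1]^2 + q[, 2]^2)
  (rho - g$ring_radius)^2 + q[, 3]^2 <= g$tube_radius^2 & q[, 2] >= 0
}

#' Compartment membership test
#'
#' Vectorised containment predicate for the volume compartments of a cell
#' model. `cytoplasm` is the cell interior excluding nucleus and Golgi.
#'
#' @param cell a `cell_model`.
#' @param pts n x 3 matrix of points, um.
#' @param compartment one of `"cell"`, `"cytoplasm"`, `"nucleus"`, `"golgi"`.
#' @return logical vector of length n.
#' @export
in_compartment <- function(cell, pts, compartment) {
  pts <- rbind(pts)
  switch(compartment,
    cell = .in_cell_boundary(cell, pts),
    nucleus = .in_nucleus(cell, pts),
    golgi = .in_golgi(cell, pts),
    cytoplasm = .in_cell_boundary(cell, pts) & !.in_nucleus(cell, pts) &
      !.in_golgi(cell, pts),
    stopf("unknown compartment '%s'", compartment))
}

# containment hierarchy check by dense surface/point sampling
.validate_cell <- function(cell, n = 4000) {
  # nucleus surface strictly inside the cell boundary
  u <- runif_directions(n)
  npts <- sweep(u %*% diag(cell$nucleus$semi * 0.999), 2, cell$nucleus$centre, "+")
  if (!all(.in_cell_boundary(cell, npts)))
    stopf("geometry error: nucleus not strictly inside the cell boundary")
  if (!is.null(cell$golgi)) {
    g <- cell$golgi
    phi <- stats::runif(n, -pi / 2, pi / 2)  # kept half: y >= centre y
    th <- stats::runif(n, 0, 2 * pi)
    rho <- g$ring_radius + g$tube_radius * 0.999 * cos(th)
    gpts <- cbind(rho * sin(phi), rho * cos(phi),
                  g$tube_radius * 0.999 * sin(th))
    gpts <- sweep(gpts, 2, g$centre, "+")
    if (!all(.in_cell_boundary(cell, gpts)))
      stopf("geometry error: Golgi not inside the cell boundary")
    if (any(.in_nucleus(cell, gpts)))
      stopf("geometry error: Golgi intersects the nucleus")
  }
  invisible(cell)
}

# bounding box (2 x 3 matrix) of a compartment for rejection sampling
.compartment_bbox <- function(cell, compartment) {
  if (cell$shape == "mesh") {
    m <- switch(compartment, nucleus = cell$meshes$nucleus,
                golgi = cell$meshes$golgi, cell$meshes$cytoplasm)
    return(rbind(apply(m$vertices, 2, min), apply(m$vertices, 2, max)))
  }
  if (compartment == "nucleus") {
    c0 <- cell$nucleus$centre; s <- cell$nucleus$semi
    return(rbind(c0 - s, c0 + s))
  }
  if (compartment == "golgi") {
    g <- cell$golgi
    if (is.null(g)) stopf("cell has no Golgi compartment")
    ext <- g$ring_radius + g$tube_radius
    return(rbind(g$centre + c(-ext, 0, -g$tube_radius),
                 g$centre + c(ext, ext, g$tube_radius)))
  }
  switch(cell$shape,
    sphere = rbind(cell$centre - cell$R_cell, cell$centre + cell$R_cell),
    truncated_cone = rbind(c(-cell$base_radius, -cell$base_radius, 0),
                           c(cell$base_radius, cell$base_radius, cell$height)))
}

#' Sample points uniformly in (or on) a cell compartment
#'
#' Volume compartments are sampled by rejection within the compartment
#' bounding box; the `membrane` compartment is sampled uniformly on the cell
#' outer surface (area-weighted over base disc, top disc and lateral surface
#' for the truncated cone; area-weighted triangles for meshes).
#'
#' @param cell a `cell_model`.
#' @param compartment `"cytoplasm"`, `"nucleus"`, `"golgi"` or `"membrane"`.
#' @param n number of points.
#' @param seed optional seed.
#' @return n x 3 matrix of points, um.
#' @export
sample_point_in_compartment <- function(cell, compartment, n = 1, seed = NULL) {
  with_seed(seed, {
    if (compartment == "membrane") return(.sample_membrane(cell, n))
    bb <- .compartment_bbox(cell, compartment)
    out <- matrix(0, 0, 3)
    tried <- 0; got <- 0
    while (got < n) {
      m <- max(2L * (n - got), 1000L)
      cand <- cbind(stats::runif(m, bb[1, 1], bb[2, 1]),
                    stats::runif(m, bb[1, 2], bb[2, 2]),
                    stats::runif(m, bb[1, 3], bb[2, 3]))
      keep <- in_compartment(cell, cand, compartment)
      tried <- tried + m; got <- got + sum(keep)
      out <- rbind(out, cand[keep, , drop = FALSE])
      if (tried > 1e4 && got / tried < 1e-4)
        stopf("degenerate geometry: rejection acceptance rate < 1e-4 for '%s'",
              compartment)
    }
    out[seq_len(n), , drop = FALSE]
  })
}

.sample_membrane <- function(cell, n) {
  if (cell$shape == "sphere") {
    return(sweep(runif_directions(n) * cell$R_cell, 2, cell$centre, "+"))
  }
  if (cell$shape == "mesh") {
    return(sample_on_mesh(cell$meshes$cytoplasm, n))
  }
  rb <- cell$base_radius; rt <- cell$top_radius; h <- cell$height
  slant <- sqrt(h^2 + (rb - rt)^2)
  areas <- c(base = pi * rb^2, top = pi * rt^2, lateral = pi * (rb + rt) * slant)
  part <- sample(3, n, replace = TRUE, prob = areas)
  out <- matrix(0, n, 3)
  for (p in 1:3) {
    idx <- which(part == p); m <- length(idx)
    if (m == 0) next
    if (p <= 2) {  # discs
      r <- (if (p == 1) rb else rt) * sqrt(stats::runif(m))
      a <- stats::runif(m, 0, 2 * pi)
      out[idx, ] <- cbind(r * cos(a), r * sin(a), if (p == 1) 0 else h)
    } else {       # lateral: area density along z proportional to r(z)
      u <- stats::runif(m)
      # invert CDF of linear density r(z) = rb + (rt-rb) z/h
      cdf_tot <- (rb + rt) / 2
      z <- if (abs(rt - rb) < 1e-12) u * h else
        h * (rb - sqrt(rb^2 - u * cdf_tot * 2 * (rb - rt))) / (rb - rt)
      r <- rb + (rt - rb) * z / h
      a <- stats::runif(m, 0, 2 * pi)
      out[idx, ] <- cbind(r * cos(a), r * sin(a), z)
    }
  }
  out
}

# ---- layouts ----------------------------------------------------------------

.hex_lattice <- function(pitch, rmax) {
  jmax <- ceiling(rmax / (pitch * sqrt(3) / 2)) + 1
  imax <- ceiling(rmax / pitch) + 1
  ij <- expand.grid(i = -imax:imax, j = -jmax:jmax)
  x <- (ij$i + ij$j / 2) * pitch
  y <- ij$j * pitch * sqrt(3) / 2
  d <- sqrt(x^2 + y^2)
  keep <- d <= rmax & d > 1e-9
  cbind(x = x[keep], y = y[keep])
}

#' Hexagonal monolayer layout
#'
#' Enumerates the neighbour cells of a target cell at the origin of a
#' hexagonal (densest-packing) monolayer on the z = 0 plane. `gap` is the
#' edge-to-edge spacing in units of the cell footprint diameter, so the
#' lattice pitch is `footprint * (1 + gap)`; `gap = 0` means touching cells.
#' All neighbours whose centres lie within `cutoff_um` of the target are
#' listed (default 280 um, the average range of the Lu-177 beta spectrum
#' used as the source-inclusion cutoff).
#'
#' @param cell a `cell_model` (provides the footprint diameter).
#' @param gap edge-to-edge spacing, cell diameters (>= 0).
#' @param cutoff_um neighbour cutoff radius, um.
#' @return object of class `monolayer_layout` with fields `positions`
#'   (m x 2 xy matrix), `pitch`, `gap`, `cutoff_um`.
#' @export
layout_monolayer <- function(cell, gap = 0, cutoff_um = 280) {
  if (gap < 0) stopf("gap must be >= 0")
  pitch <- cell$footprint_diameter * (1 + gap)
  pos <- .hex_lattice(pitch, cutoff_um)
  structure(list(positions = pos, pitch = pitch, gap = gap,
                 cutoff_um = cutoff_um,
                 footprint = cell$footprint_diameter),
            class = "monolayer_layout")
}

#' Compact colony cluster layout
#'
#' Positions of the other `size - 1` cells of a compact (touching, gap 0)
#' hexagonal cluster containing the target cell, used for the colony-forming
#' follow-up days where only a cell's own progeny contribute cross-dose.
#'
#' @param cell a `cell_model`.
#' @param size cluster size in cells (>= 1).
#' @return a `monolayer_layout` whose `positions` are the `size - 1`
#'   neighbour sites nearest the target.
#' @export
layout_cluster <- function(cell, size) {
  if (size < 1) stopf("cluster size must be >= 1")
  pitch <- cell$footprint_diameter
  if (size == 1) {
    pos <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y")))
  } else {
    lat <- .hex_lattice(pitch, pitch * (2 + ceiling(sqrt(size))))
    d <- sqrt(rowSums(lat^2))
    ord <- order(d, atan2(lat[, 2], lat[, 1]))
    pos <- lat[ord[seq_len(size - 1)], , drop = FALSE]
  }
  structure(list(positions = pos, pitch = pitch, gap = 0,
                 cutoff_um = NA_real_, footprint = cell$footprint_diameter,
                 cluster_size = size),
            class = "monolayer_layout")
}

#' @export
print.monolayer_layout <- function(x, ...) {
  cat(sprintf("<monolayer_layout> %d source cells, pitch %.1f um (gap %.1f dia)\n",
              nrow(x$positions), x$pitch, x$gap))
  invisible(x)
}

#' Medium-filled culture well
#'
#' Cylindrical well holding the radioactive growth medium; the reference
#' cell adheres to the bottom centre. Defaults match one well of a 12-well
#' plate (radius 11.05 mm).
#'
#' @param volume_ml medium volume, ml.
#' @param radius_mm well radius, mm.
#' @return object of class `well_geometry` with heights in mm and um.
#' @export
build_well <- function(volume_ml = 1, radius_mm = 11.05) {
  if (volume_ml <= 0 || radius_mm <= 0) stopf("volume and radius must be > 0")
  height_mm <- volume_ml * 1000 / (pi * radius_mm^2)
  structure(list(volume_ml = volume_ml, radius_mm = radius_mm,
                 height_mm = height_mm,
                 radius_um = radius_mm * 1000, height_um = height_mm * 1000,
                 volume_um3 = volume_ml * 1e12),
            class = "well_geometry")
}

#' @export
print.well_geometry <- function(x, ...) {
  cat(sprintf("<well_geometry> r = %.2f mm, medium height %.2f mm (%.3g ml)\n",
              x$radius_mm, x$height_mm, x$volume_ml))
  invisible(x)
}
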