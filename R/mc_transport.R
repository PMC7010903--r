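# Straight-line CSDA Monte Carlo engine for cellular S values: energy
# deposited in the nucleus per decay in a source compartment, for single
# cells (self-dose), monolayers/clusters (cross-dose) and the medium-filled
# well. Electrons travel in straight lines, losing energy continuously at
# the collisional stopping-power rate, and stop at their CSDA range; no
# scattering, delta-rays or straggling. The whole problem is one material
# (water): the membrane is a zero-thickness surface and the bulk
# compartments are water-equivalent.

.s_value_obj <- function(dep_keV, yield, mass_kg, source, n, seed, meta = list()) {
  conv <- yield * KEV_TO_J / mass_kg
  structure(c(list(
    value = mean(dep_keV) * conv,
    se = stats::sd(dep_keV) / sqrt(length(dep_keV)) * conv,
    source = source, target = "nucleus",
    n_histories = n, seed = seed), meta),
    class = "s_value")
}

#' @export
print.s_value <- function(x, ...) {
  cat(sprintf("<s_value> N <- %s: %.4g +/- %.2g Gy/(Bq s)  [%g histories]\n",
              x$source, x$value, x$se, x$n_histories))
  invisible(x)
}

# Energy deposited in the target nucleus for each ray (keV).
# origins/dirs in the target cell's frame.
.nucleus_deposit <- function(cell, origins, dirs, E_keV, material) {
  R <- csda_range(E_keV, material)
  if (cell$nucleus$type == "ellipsoid") {
    ctr <- cell$nucleus$centre; s <- cell$nucleus$semi
    q1 <- (origins[, 1] - ctr[1]) / s[1]
    q2 <- (origins[, 2] - ctr[2]) / s[2]
    q3 <- (origins[, 3] - ctr[3]) / s[3]
    v1 <- dirs[, 1] / s[1]; v2 <- dirs[, 2] / s[2]; v3 <- dirs[, 3] / s[3]
    A <- v1^2 + v2^2 + v3^2
    B <- 2 * (q1 * v1 + q2 * v2 + q3 * v3)
    C <- q1^2 + q2^2 + q3^2 - 1
    disc <- B^2 - 4 * A * C
    dep <- numeric(nrow(origins))
    hit <- disc > 0
    if (any(hit)) {
      sq <- sqrt(disc[hit])
      t1 <- (-B[hit] - sq) / (2 * A[hit])
      t2 <- (-B[hit] + sq) / (2 * A[hit])
      Rh <- R[hit]
      t1c <- pmin(pmax(t1, 0), Rh)
      t2c <- pmin(pmax(t2, 0), Rh)
      dep[hit] <- residual_energy(Rh - t1c, material) -
        residual_energy(Rh - t2c, material)
    }
    return(dep)
  }
  # mesh nucleus: signed-crossing accumulation; entering crossings add the
  # residual energy at the crossing, exiting crossings subtract it, and an
  # origin inside the surface (odd crossing parity) adds the full energy.
  hits <- .ray_mesh_hits(origins, dirs, cell$meshes$nucleus)
  n <- nrow(origins)
  dep <- numeric(n)
  if (length(hits$ray)) {
    eres <- residual_energy(pmax(R[hits$ray] - hits$t, 0), material)
    rs <- rowsum(hits$sgn * eres, hits$ray)
    dep[as.integer(rownames(rs))] <- rs[, 1]
    inside <- tabulate(hits$ray, nbins = n) %% 2 == 1
    dep[inside] <- dep[inside] + E_keV[inside]
  }
  pmax(dep, 0)
}

#' Energy deposited in the nucleus along straight electron tracks
#'
#' The CSDA transport kernel: an electron of energy `E_keV` starts at
#' `origin` and travels along `direction`; the energy deposited inside the
#' target cell's nucleus is the difference of residual energies at the
#' chord entry and exit points (range-energy inversion), zero if the track
#' misses the nucleus, and the full residual energy at entry if the
#' electron stops inside.
#'
#' @param origin,direction n x 3 matrices (direction rows unit-length), um.
#' @param E_keV electron energies, keV (length n).
#' @param cell target `cell_model` (its nucleus is the tally region).
#' @param material transport material (default water).
#' @return energy deposited in the nucleus per track, keV.
#' @export
deposit_along_ray <- function(origin, direction, E_keV, cell,
                              material = material_water()) {
  origin <- rbind(origin); direction <- rbind(direction)
  nrm <- sqrt(rowSums(direction^2))
  if (any(abs(nrm - 1) > 1e-6)) stopf("direction rows must be unit-length")
  .nucleus_deposit(cell, origin, direction, E_keV, material)
}

# uniform directions within cones of half-angle acos(cos_th) about per-row
# axes (cos_th = -1 gives the full sphere)
.sample_cone <- function(axis, cos_th) {
  n <- nrow(axis)
  mu <- cos_th + stats::runif(n) * (1 - cos_th)
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(pmax(1 - mu^2, 0))
  # orthonormal frame about each axis
  h <- ifelse(abs(axis[, 1]) < 0.9, 1, 0)
  ref <- cbind(h, 1 - h, 0)
  u <- cbind(axis[, 2] * ref[, 3] - axis[, 3] * ref[, 2],
             axis[, 3] * ref[, 1] - axis[, 1] * ref[, 3],
             axis[, 1] * ref[, 2] - axis[, 2] * ref[, 1])
  u <- u / pmax(sqrt(rowSums(u^2)), 1e-12)
  v <- cbind(axis[, 2] * u[, 3] - axis[, 3] * u[, 2],
             axis[, 3] * u[, 1] - axis[, 1] * u[, 3],
             axis[, 1] * u[, 2] - axis[, 2] * u[, 1])
  axis * mu + u * (s * cos(phi)) + v * (s * sin(phi))
}

.nucleus_mass_kg <- function(cell, density = 1.0)
  cell$volumes$nucleus * density * UM3_TO_KG

.source_points <- function(cell, source, n) {
  comp <- switch(source,
    cytoplasm = "cytoplasm", membrane = "membrane", golgi = "golgi",
    nucleus = "nucleus",
    stopf("unknown source compartment '%s'", source))
  sample_point_in_compartment(cell, comp, n)
}

#' Self-dose S value by Monte Carlo
#'
#' Absorbed dose to the nucleus per decay (Gy per Bq s) for a radioactive
#' source uniformly distributed in one compartment of the same cell. Each
#' history samples an emission energy from the spectrum (all emissions
#' weighted by their yields), a uniform source point and an isotropic
#' direction, and tallies the chord energy deposit in the nucleus.
#'
#' @param cell a `cell_model`.
#' @param source `"cytoplasm"`, `"membrane"`, `"golgi"`, or `"nucleus"`
#'   (validation: full-absorption limit).
#' @param n_histories number of decays to simulate.
#' @param seed integer seed (fixed seed gives a bit-identical tally).
#' @param spectrum an `emission_spectrum` (default packaged Lu-177).
#' @param material transport material (default water).
#' @return an `s_value` with Monte Carlo standard error.
#' @export
self_s_value <- function(cell, source, n_histories = 1e5, seed = 1,
                         spectrum = load_emission_spectrum(),
                         material = material_water()) {
  if (cell$volumes$nucleus <= 0) stopf("zero nucleus volume")
  with_seed(seed, {
    E <- sample_electron(spectrum, n_histories)
    org <- .source_points(cell, source, n_histories)
    dirs <- runif_directions(n_histories)
    dep <- .nucleus_deposit(cell, org, dirs, E, material)
    .s_value_obj(dep, spectrum$total_yield, .nucleus_mass_kg(cell),
                 source, n_histories, seed, list(kind = "self"))
  })
}

#' Total cross-dose S value from a cell layout
#'
#' Dose to the target cell's nucleus per decay in the selected compartment
#' of each surrounding cell (activity 1 Bq s per source cell, the same
#' per-cell normalisation as the self-dose). Histories are split evenly over
#' the source cells, so the total is exactly the sum of the per-neighbour
#' S values (retrievable via `$per_neighbour`).
#'
#' @param cell the cell model (identical for target and sources).
#' @param layout a `monolayer_layout` (neighbour positions).
#' @param source source compartment in the neighbouring cells.
#' @inheritParams self_s_value
#' @return an `s_value`; `$per_neighbour` is a data frame (x, y, value, se).
#' @export
cross_s_value <- function(cell, layout, source, n_histories = 1e5, seed = 1,
                          spectrum = load_emission_spectrum(),
                          material = material_water()) {
  pos <- layout$positions
  m <- nrow(pos)
  if (m == 0) {
    return(structure(list(value = 0, se = 0, source = source,
                          target = "nucleus", n_histories = 0, seed = seed,
                          kind = "cross",
                          per_neighbour = data.frame(x = numeric(0), y = numeric(0),
                                                     value = numeric(0), se = numeric(0))),
                     class = "s_value"))
  }
  n_per <- max(10L, ceiling(n_histories / m))
  ntot <- n_per * m
  with_seed(seed, {
    # chunked over histories to bound memory at large n
    block <- 2e6
    sum1 <- numeric(m); sum2 <- numeric(m)
    for (lo in seq(1, ntot, by = block)) {
      hi <- min(ntot, lo + block - 1)
      nb <- hi - lo + 1
      idx <- ((lo:hi) - 1L) %/% n_per + 1L
      E <- sample_electron(spectrum, nb)
      org <- .source_points(cell, source, nb)
      org[, 1] <- org[, 1] + pos[idx, 1]
      org[, 2] <- org[, 2] + pos[idx, 2]
      dirs <- runif_directions(nb)
      dep <- .nucleus_deposit(cell, org, dirs, E, material)
      rs <- rowsum(cbind(dep, dep^2), idx)
      at <- as.integer(rownames(rs))
      sum1[at] <- sum1[at] + rs[, 1]
      sum2[at] <- sum2[at] + rs[, 2]
    }
    conv <- spectrum$total_yield * KEV_TO_J / .nucleus_mass_kg(cell)
    pm <- sum1 / n_per
    pv <- sum2 / n_per
    per_se <- sqrt(pmax(pv - pm^2, 0) / n_per) * conv
    per_val <- pm * conv
    res <- structure(list(
      value = sum(per_val), se = sqrt(sum(per_se^2)),
      source = source, target = "nucleus",
      n_histories = ntot, seed = seed, kind = "cross",
      n_source_cells = m, histories_per_cell = n_per,
      per_neighbour = data.frame(x = pos[, 1], y = pos[, 2],
                                 value = as.numeric(per_val),
                                 se = as.numeric(per_se))),
      class = "s_value")
    res
  })
}

#' Medium-source S value for the culture well
#'
#' Dose to the nucleus per decay uniformly distributed in the whole medium
#' volume of the well. Two exact importance-sampling devices keep the
#' variance of this very small quantity manageable: (1) source points are
#' drawn with density proportional to \eqn{1/r^2} around the nucleus centre
#' (uniform radius within the maximum CSDA range), each history carrying
#' the weight \eqn{4\pi r^2 R_{max} / V_M}; points falling outside the
#' medium (outside the cylinder, below the bottom, above the surface, or
#' inside the cell) score zero; (2) emission directions are sampled
#' uniformly within the cone subtending the nucleus bounding sphere, with
#' the solid-angle weight \eqn{(1 - \cos\theta)/2} - under straight-line
#' transport a direction outside that cone deposits exactly zero. Decays
#' beyond the maximum range cannot reach the nucleus and are represented by
#' the analytic weight, not simulated.
#'
#' @param cell a `cell_model` adherent at the bottom centre.
#' @param well a `well_geometry`.
#' @param cell_base_z height of the cell base above the well bottom, um
#'   (default 0: adherent; raise it to validate the charged-particle
#'   equilibrium limit away from boundaries).
#' @inheritParams self_s_value
#' @return an `s_value`; `$weight_scheme` documents the importance weight.
#' @export
medium_s_value <- function(cell, well, n_histories = 2e5, seed = 1,
                           spectrum = load_emission_spectrum(),
                           material = material_water(),
                           cell_base_z = 0) {
  e_max <- max(c(vapply(spectrum$branches, function(b) b$endpoint, 0),
                 spectrum$lines$energy_keV))
  rmax <- csda_range(e_max, material)
  ctr <- cell$nucleus$centre + c(0, 0, cell_base_z)
  with_seed(seed, {
    E <- sample_electron(spectrum, n_histories)
    r <- stats::runif(n_histories) * rmax
    w <- runif_directions(n_histories)
    org <- cbind(ctr[1] + r * w[, 1], ctr[2] + r * w[, 2], ctr[3] + r * w[, 3])
    inside_medium <- org[, 3] >= 0 & org[, 3] <= well$height_um &
      (org[, 1]^2 + org[, 2]^2) <= well$radius_um^2
    local <- org
    local[, 3] <- local[, 3] - cell_base_z
    in_cell <- .in_cell_boundary(cell, local)
    valid <- inside_medium & !in_cell
    # cone-restricted directions: bounding-sphere radius of the nucleus
    rb <- if (cell$nucleus$type == "ellipsoid") max(cell$nucleus$semi)
          else max(sqrt(rowSums(sweep(cell$meshes$nucleus$vertices, 2,
                                      cell$nucleus$centre)^2)))
    cos_th <- ifelse(r > rb, sqrt(pmax(1 - (rb / r)^2, 0)), -1)
    w_dir <- (1 - cos_th) / 2
    axis <- cbind(ctr[1] - org[, 1], ctr[2] - org[, 2], ctr[3] - org[, 3])
    axis <- axis / pmax(sqrt(rowSums(axis^2)), 1e-12)
    dirs <- .sample_cone(axis, cos_th)
    dep <- numeric(n_histories)
    if (any(valid)) {
      # deposits computed in the cell frame (source shifted down by the
      # cell base height)
      dep[valid] <- .nucleus_deposit(cell, local[valid, , drop = FALSE],
                                     dirs[valid, , drop = FALSE],
                                     E[valid], material)
    }
    wgt <- 4 * pi * r^2 * rmax / well$volume_um3 * w_dir
    contrib <- dep * wgt
    res <- .s_value_obj(contrib, spectrum$total_yield, .nucleus_mass_kg(cell),
                        "medium", n_histories, seed,
                        list(kind = "medium",
                             weight_scheme = "w = 4*pi*r^2*Rmax/V_M, r ~ U(0, Rmax) about the nucleus centre",
                             rmax_um = rmax))
    res
  })
}

#' Parameter sweeps of cellular S values
#'
#' Reproduces the S-value parameter analyses over the truncated-cone cell
#' family: cell-volume trend, source-location comparison, nucleus-position
#' shifts, and cell-proximity (gap) decay of the cross-dose.
#'
#' @param type one of `"volume"`, `"source"`, `"nucleus_offset"`, `"gap"`.
#' @param values sweep grid: cell volumes (um^3), source names, y-shifts
#'   (um), or gaps (cell diameters).
#' @param volume cell volume used when the sweep is not over volume.
#' @param source source compartment used when not swept.
#' @param cross also compute the touching-monolayer total cross-dose
#'   (always on for `type = "gap"`).
#' @param cutoff_um neighbour cutoff for cross-dose layouts.
#' @inheritParams self_s_value
#' @return data frame with one row per grid point: `value` of the sweep
#'   variable, `s_self`, `se_self` and (when requested) `s_cross`,
#'   `se_cross` in Gy/(Bq s).
#' @export
parameter_sweep <- function(type = c("volume", "source", "nucleus_offset", "gap"),
                            values, volume = 3480, source = "cytoplasm",
                            cross = FALSE, cutoff_um = 280,
                            n_histories = 2e4, seed = 1,
                            spectrum = load_emission_spectrum(),
                            material = material_water()) {
  type <- match.arg(type)
  rows <- lapply(seq_along(values), function(i) {
    v <- values[[i]]
    sd_i <- seed + i
    cell <- switch(type,
      volume = tc_cell(v),
      source = tc_cell(volume),
      nucleus_offset = tc_cell(volume, nucleus_offset = c(v, 0)),
      gap = tc_cell(volume))
    src <- if (type == "source") v else source
    out <- data.frame(value = if (type == "source") NA_real_ else v,
                      stringsAsFactors = FALSE)
    if (type == "source") out$source <- v else out$source <- src
    if (type != "gap") {
      s <- self_s_value(cell, src, n_histories, sd_i, spectrum, material)
      out$s_self <- s$value; out$se_self <- s$se
    }
    if (cross || type == "gap") {
      gap <- if (type == "gap") v else 0
      lay <- layout_monolayer(cell, gap = gap, cutoff_um = cutoff_um)
      cs <- cross_s_value(cell, lay, src, n_histories, sd_i + 1000L,
                          spectrum, material)
      out$s_cross <- cs$value; out$se_cross <- cs$se
      out$n_neighbours <- nrow(lay$positions)
    }
    out
  })
  do.call(rbind, rows)
}

#' Exponential trend fit for S-value sweeps
#'
#' Fits \eqn{S = a e^{-bV}} by least squares on \eqn{\log S} and reports the
#' coefficient of determination, the goodness measure quoted for the
#' volume dependence of self- and cross-dose.
#'
#' @param x sweep variable (e.g. cell volume, um^3).
#' @param s S values (> 0).
#' @return list with `a`, `b`, `r_squared`, and the fitted `lm`.
#' @export
fit_exponential_trend <- function(x, s) {
  if (any(s <= 0)) stopf("S values must be positive for the exponential fit")
  fit <- stats::lm(log(s) ~ x)
  list(a = exp(unname(stats::coef(fit)[1])), b = -unname(stats::coef(fit)[2]),
       r_squared = summary(fit)$r.squared, fit = fit)
}
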