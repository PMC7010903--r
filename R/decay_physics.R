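# Electron emission physics for Lu-177: emission spectrum handling and
# range-energy relations in water / lipid under the continuous-slowing-down
# approximation (CSDA).

MEC2_KEV <- 510.99895  # electron rest energy

# Relativistic Bethe collisional stopping power, MeV cm^2/g.
# T_keV kinetic energy; I_eV mean excitation energy; z_over_a = <Z/A>.
# No density-effect correction (negligible below ~1 MeV in water).
.bethe_mass_stopping <- function(T_keV, I_eV = 78, z_over_a = 0.5551) {
  tau <- T_keV / MEC2_KEV
  beta2 <- 1 - 1 / (1 + tau)^2
  i_ratio <- (I_eV * 1e-3) / MEC2_KEV
  lnterm <- log(tau^2 * (tau + 2) / (2 * i_ratio^2))
  ftau <- 1 - beta2 + (tau^2 / 8 - (2 * tau + 1) * log(2)) / (tau + 1)^2
  0.153536 * z_over_a / beta2 * (lnterm + ftau)
}

.material_from_table <- function(name, density, energy_keV, sp_keV_um) {
  if (any(!is.finite(sp_keV_um)) || any(sp_keV_um <= 0))
    stopf("stopping power must be positive and finite for material '%s'", name)
  if (is.unsorted(energy_keV, strictly = TRUE))
    stopf("stopping-power energy grid must be strictly increasing")
  # cumulative CSDA range by trapezoidal integration of 1/S;
  # contribution below the first grid point taken as E_min / S(E_min)
  inv <- 1 / sp_keV_um
  r0 <- energy_keV[1] * inv[1]
  range_um <- r0 + c(0, cumsum(diff(energy_keV) * (utils::head(inv, -1) + utils::tail(inv, -1)) / 2))
  structure(list(name = name, density_g_cm3 = density,
                 energy_keV = energy_keV, sp_keV_um = sp_keV_um,
                 range_um = range_um),
            class = "material_model")
}

#' Material models for electron transport
#'
#' Builds a material with a collisional stopping-power table (keV/um) and the
#' CSDA range table derived from it by integration. `material_water()` uses
#' the relativistic Bethe formula with mean excitation energy 78 eV and
#' density 1 g/cm^3; `material_lipid()` is the density-scaled water table at
#' 0.92 g/cm^3 (cell-membrane lipid). A user table can be supplied with
#' `load_stopping_power()` (CSV columns `energy_keV`, `S_keV_per_um`).
#'
#' @param e_max_keV upper end of the energy grid (default 800 keV, above the
#'   hardest Lu-177 beta endpoint).
#' @param n_grid number of log-spaced grid points.
#' @return object of class `material_model`.
#' @export
material_water <- function(e_max_keV = 800, n_grid = 500) {
  e <- exp(seq(log(0.2), log(e_max_keV), length.out = n_grid))
  sp <- .bethe_mass_stopping(e) * 0.1  # MeV cm^2/g * rho(1 g/cm^3) -> keV/um
  .material_from_table("water", 1.0, e, sp)
}

#' @rdname material_water
#' @export
material_lipid <- function(e_max_keV = 800, n_grid = 500) {
  w <- material_water(e_max_keV, n_grid)
  .material_from_table("lipid", 0.92, w$energy_keV, w$sp_keV_um * 0.92)
}

#' @rdname material_water
#' @param path CSV file with columns `energy_keV`, `S_keV_per_um`.
#' @param name,density material name and density in g/cm^3.
#' @export
load_stopping_power <- function(path, name = "custom", density = 1.0) {
  tab <- utils::read.csv(path)
  if (!all(c("energy_keV", "S_keV_per_um") %in% names(tab)))
    stopf("stopping-power CSV needs columns energy_keV, S_keV_per_um")
  .material_from_table(name, density, tab$energy_keV, tab$S_keV_per_um)
}

#' @export
print.material_model <- function(x, ...) {
  cat(sprintf("<material_model> %s (rho = %.2f g/cm3), %d-point table %.3g-%.4g keV\n",
              x$name, x$density_g_cm3, length(x$energy_keV),
              min(x$energy_keV), max(x$energy_keV)))
  invisible(x)
}

#' CSDA range and its inverse
#'
#' `csda_range()` returns the continuous-slowing-down range
#' \eqn{\int_0^E dE'/S(E')} in micrometres; `residual_energy()` is the
#' inverse lookup: the kinetic energy of an electron whose remaining range is
#' `range_um`. Both interpolate the material's tables; energies above the
#' table maximum are an error (no extrapolation).
#'
#' @param E_keV electron kinetic energy (vectorised), keV.
#' @param material a `material_model`.
#' @return range in micrometres (or energy in keV for `residual_energy`).
#' @export
csda_range <- function(E_keV, material) {
  if (any(E_keV < 0)) stopf("energy must be >= 0")
  if (any(E_keV > max(material$energy_keV)))
    stopf("energy %.4g keV above stopping-power table maximum (%.4g keV)",
          max(E_keV), max(material$energy_keV))
  out <- numeric(length(E_keV))
  pos <- E_keV > 0
  if (any(pos)) {
    # below the grid minimum: linear in E with slope 1/S(E_min)
    small <- pos & E_keV < material$energy_keV[1]
    big <- pos & !small
    out[small] <- E_keV[small] / material$sp_keV_um[1]
    if (any(big))
      out[big] <- stats::approx(material$energy_keV, material$range_um,
                                xout = E_keV[big])$y
  }
  out
}

#' @rdname csda_range
#' @param range_um remaining path length, micrometres (vectorised).
#' @export
residual_energy <- function(range_um, material) {
  out <- numeric(length(range_um))
  pos <- range_um > 0
  r1 <- material$range_um[1]
  small <- pos & range_um < r1
  big <- pos & !small
  out[small] <- range_um[small] * material$sp_keV_um[1]
  if (any(big))
    out[big] <- stats::approx(material$range_um, material$energy_keV,
                              xout = range_um[big], rule = 2)$y
  out
}

# ---- emission spectrum ------------------------------------------------------

# Allowed-shape beta spectral density with a non-relativistic Coulomb (Fermi)
# correction for the daughter nucleus charge. Returns unnormalised density
# over the energy grid.
.beta_allowed_density <- function(T_keV, Q_keV, z_daughter = 72) {
  tau <- T_keV / MEC2_KEV
  w <- tau + 1
  p <- sqrt(pmax(tau * (tau + 2), 1e-12))
  eta <- (1 / 137.036) * z_daughter * w / p
  fermi <- 2 * pi * eta / (1 - exp(-2 * pi * eta))
  d <- p * w * (Q_keV - T_keV)^2 * fermi
  d[T_keV >= Q_keV | T_keV <= 0] <- 0
  d
}

.trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Load an electron emission spectrum
#'
#' Reads an emission table (CSV columns `type` in `beta`/`discrete`/
#' `beta_density`, `energy_keV`, `yield`, `density`) and returns an
#' `emission_spectrum`. `beta` rows give a branch endpoint energy and branch
#' yield per decay; the spectral density defaults to the allowed-shape Fermi
#' approximation and can be overridden by `beta_density` rows (tabulated
#' density points attached to the preceding `beta` row). `discrete` rows are
#' internal-conversion / Auger lines. Electrons below `cutoff_keV` are
#' excluded from sampling and from the per-decay mean energy (they travel
#' well under a micrometre in water).
#'
#' The default table (`path = NULL`) is the packaged compiled approximation
#' of the Lu-177 electron output: three dominant beta branches (endpoints
#' ~498/385/177 keV) plus the main conversion-electron and Auger lines.
#'
#' @param path CSV path, or `NULL` for the packaged Lu-177 table.
#' @param cutoff_keV low-energy sampling cutoff (default 3.8 keV).
#' @return an `emission_spectrum`: beta branches with normalised tabulated
#'   densities, discrete lines, `delta_keV` (mean emitted electron energy per
#'   decay above the cutoff, computed by quadrature) and `total_yield`
#'   (electrons per decay above the cutoff).
#' @export
load_emission_spectrum <- function(path = NULL, cutoff_keV = 3.8) {
  if (cutoff_keV < 0) stopf("cutoff must be >= 0")
  if (is.null(path))
    path <- system.file("extdata", "lu177_electron_spectrum.csv",
                        package = "celldose", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("type", "energy_keV", "yield")
  if (!all(need %in% names(tab)))
    stopf("emission table needs columns %s", paste(need, collapse = ", "))
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    if (!r$type %in% c("beta", "discrete", "beta_density"))
      stopf("emission table row %d: unknown type '%s'", i, r$type)
    if (!is.finite(r$energy_keV) || r$energy_keV <= 0)
      stopf("emission table row %d: bad energy", i)
    if (r$type != "beta_density" && (!is.finite(r$yield) || r$yield < 0))
      stopf("emission table row %d: missing or negative yield", i)
  }

  branches <- list(); beta <- NULL; cur <- 0L
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    if (r$type == "beta") {
      cur <- cur + 1L
      beta <- rbind(beta, data.frame(endpoint_keV = r$energy_keV, yield = r$yield))
      branches[[cur]] <- list(endpoint = r$energy_keV, yield = r$yield,
                              density = NULL)
    } else if (r$type == "beta_density") {
      if (cur == 0L) stopf("beta_density row %d precedes any beta branch", i)
      branches[[cur]]$density <- rbind(branches[[cur]]$density,
                                       c(r$energy_keV, r$density))
    }
  }
  lines <- tab[tab$type == "discrete", c("energy_keV", "yield")]

  # per-branch normalised density + truncated CDF above the cutoff
  branches <- lapply(branches, function(b) {
    if (is.null(b$density)) {
      e <- seq(0, b$endpoint, length.out = 600)
      d <- .beta_allowed_density(e, b$endpoint)
    } else {
      e <- b$density[, 1]; d <- b$density[, 2]
      if (any(d < 0)) stopf("negative beta spectral density")
    }
    norm <- .trapz(e, d)
    if (!is.finite(norm) || norm <= 0) stopf("beta branch density not integrable")
    d <- d / norm
    above <- e >= cutoff_keV
    if (!any(above)) {
      b$p_above <- 0; b$mean_above <- 0
    } else {
      ea <- c(cutoff_keV, e[e > cutoff_keV])
      da <- stats::approx(e, d, xout = ea)$y
      b$p_above <- .trapz(ea, da)
      b$mean_above <- .trapz(ea, ea * da) / b$p_above
      cdf <- c(0, cumsum(diff(ea) * (utils::head(da, -1) + utils::tail(da, -1)) / 2))
      b$cdf_e <- ea; b$cdf <- cdf / cdf[length(cdf)]
    }
    b$grid_e <- e; b$grid_d <- d
    b
  })

  keep <- lines$energy_keV >= cutoff_keV
  lines_kept <- lines[keep, , drop = FALSE]

  beta_eff <- vapply(branches, function(b) b$yield * b$p_above, 0)
  y_eff <- sum(beta_eff) + sum(lines_kept$yield)
  if (y_eff <= 0) stopf("no emissions above the cutoff")
  delta <- sum(vapply(branches, function(b) b$yield * b$p_above * b$mean_above, 0)) +
    sum(lines_kept$energy_keV * lines_kept$yield)

  structure(list(beta = beta, branches = branches, lines = lines_kept,
                 lines_all = lines, cutoff_keV = cutoff_keV,
                 total_yield = y_eff, delta_keV = delta,
                 comp_prob = c(beta_eff, lines_kept$yield) / y_eff),
            class = "emission_spectrum")
}

#' @export
print.emission_spectrum <- function(x, ...) {
  cat(sprintf(paste0("<emission_spectrum> %d beta branch(es), %d discrete line(s)\n",
                     "  cutoff %.2f keV | yield above cutoff %.3f e-/decay | ",
                     "mean energy Delta = %.1f keV/decay\n"),
              nrow(x$beta), nrow(x$lines), x$cutoff_keV, x$total_yield, x$delta_keV))
  invisible(x)
}

#' Sample electron emission energies
#'
#' Draws `n` electron energies per emission event from the spectrum: the
#' component (beta branch or discrete line) is chosen proportionally to its
#' yield above the cutoff, beta energies by inverse-CDF of the tabulated
#' branch density truncated at the cutoff (equivalent to rejecting and
#' resampling sub-cutoff draws).
#'
#' @param spectrum an `emission_spectrum`.
#' @param n number of samples.
#' @param seed optional integer seed for reproducible streams.
#' @return numeric vector of energies in keV (all `>= cutoff_keV`).
#' @export
sample_electron <- function(spectrum, n = 1, seed = NULL) {
  stopifnot(inherits(spectrum, "emission_spectrum"))
  if (sum(spectrum$comp_prob) <= 0) stopf("all yields zero")
  with_seed(seed, {
    nb <- length(spectrum$branches)
    comp <- sample.int(length(spectrum$comp_prob), n, replace = TRUE,
                       prob = spectrum$comp_prob)
    out <- numeric(n)
    for (j in seq_len(nb)) {
      idx <- comp == j
      if (any(idx)) {
        b <- spectrum$branches[[j]]
        out[idx] <- stats::approx(b$cdf, b$cdf_e, xout = stats::runif(sum(idx)),
                                  ties = "ordered")$y
      }
    }
    if (nrow(spectrum$lines) > 0) {
      for (j in seq_len(nrow(spectrum$lines))) {
        idx <- comp == nb + j
        out[idx] <- spectrum$lines$energy_keV[j]
      }
    }
    out
  })
}
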