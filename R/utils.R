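# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards. All Monte Carlo entry points
# funnel through this so that a seed argument gives bit-reproducible output
# without clobbering the session RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

KEV_TO_J <- 1.602176634e-16   # J per keV
UM3_TO_KG <- 1e-15            # kg per um^3 at density 1 g/cm^3

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

# uniform points on the unit sphere (n x 3 matrix)
runif_directions <- function(n) {
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Export package objects as JSON
#'
#' Serialises the summary of a `cell_model` (shape, compartment volumes,
#' footprint), a `time_activity_model`, a `dose_result` or a
#' `dose_response_fit` to a JSON file for downstream tooling.
#'
#' @param x object to export.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_json <- function(x, path) {
  out <- if (inherits(x, "cell_model")) {
    list(shape = x$shape, volumes_um3 = x$volumes,
         footprint_diameter_um = x$footprint_diameter)
  } else if (inherits(x, "dose_result")) {
    list(scenario = x$scenario, A0_Bq = x$A0_Bq, total_Gy = x$total_Gy,
         total_sd_Gy = x$total_sd_Gy, per_interval = x$per_interval)
  } else if (inherits(x, "dose_response_fit")) {
    x[c("model", "alpha", "alpha_sd", "beta", "beta_sd", "alpha_over_beta",
        "r_squared", "r_squared_log", "aic", "n")]
  } else if (inherits(x, "time_activity_model")) {
    x[c("membrane", "internalized", "time_to_95pct_h", "flagged")]
  } else stopf("no JSON exporter for class '%s'", class(x)[1])
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# quadratic-sum (independent) relative SDs
#' Combine independent relative uncertainties in quadrature
#'
#' Propagates independent relative standard deviations as
#' \eqn{\sqrt{\sum_i c_i^2}}, the rule used for the absorbed-dose error
#' budget (activity-fraction, cell-count, added-activity and S-value shape
#' components).
#'
#' @param components numeric vector of relative SDs (e.g. 0.05 for 5%).
#' @return single combined relative SD.
#' @examples
#' propagate_uncertainty(c(0.03, 0.04))  # 0.05
#' @export
propagate_uncertainty <- function(components) {
  components <- components[is.finite(components)]
  if (any(components < 0)) stopf("relative SDs must be >= 0")
  sqrt(sum(components^2))
}
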