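# Packaged reference datasets: published S values, cumulative doses and
# dose-response parameters for U2OS+SST2 cells exposed to Lu-177-DOTATATE.
# These serve as fixture inputs where raw measurements are not available
# and as cross-checks for the Monte Carlo engine's scale.

.read_ref <- function(file) {
  utils::read.csv(system.file("extdata", file, package = "celldose",
                              mustWork = TRUE),
                  comment.char = "#", stringsAsFactors = FALSE)
}

#' Reference datasets for U2OS+SST2 cellular dosimetry
#'
#' `ref_pm_self_s()`: self S values to the nucleus (Gy/(Bq s)) for the nine
#' polygonal-mesh models of imaged cells, by source compartment, with cell
#' and nucleus volumes.
#'
#' `ref_golgi_s()`: Golgi-to-nucleus S values for the polygonal-mesh and
#' half-torus CSG renderings of the Golgi.
#'
#' `ref_monolayer_s()`: mean monolayer S values (self + cross) per
#' experiment interval, directly consumable by [compute_absorbed_dose()].
#'
#' `ref_cumulative_doses()`: cumulative absorbed dose to the nucleus per
#' added activity for the four modeling scenarios (sphere, TC_Cy, PM_Cy,
#' PM_G).
#'
#' `ref_lq_params()`: linear-quadratic fit parameters for x-ray and
#' radiopharmaceutical exposure.
#'
#' @return a data frame (see above); `ref_monolayer_s()` carries
#'   `attr(,"cross_geometry") = "polygonal_mesh"`.
#' @export
ref_pm_self_s <- function() .read_ref("u2os_pm_self_svalues.csv")

#' @rdname ref_pm_self_s
#' @export
ref_golgi_s <- function() .read_ref("u2os_golgi_svalues.csv")

#' @rdname ref_pm_self_s
#' @export
ref_monolayer_s <- function() {
  out <- .read_ref("u2os_monolayer_svalues.csv")
  attr(out, "cross_geometry") <- "polygonal_mesh"
  out
}

#' @rdname ref_pm_self_s
#' @export
ref_cumulative_doses <- function() .read_ref("u2os_cumulative_doses.csv")

#' @rdname ref_pm_self_s
#' @export
ref_lq_params <- function() .read_ref("u2os_lq_parameters.csv")
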