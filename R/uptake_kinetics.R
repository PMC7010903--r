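# Time-activity kinetics: fitting uptake/retention curves per compartment,
# decay correction, inverse-distance-weighting extrapolation across added
# activities, and per-interval cumulated activities.
#
# Activity fractions are dimensionless fractions of the added activity,
# decay-corrected; compartments are medium (M), membrane-bound (CS) and
# internalized (C). The physical decay constant of Lu-177 defaults to
# ln(2) / (6.647 d).

#' Physical decay constant of Lu-177
#'
#' @param half_life_d half-life in days (default 6.647).
#' @return decay constant in 1/h.
#' @export
lu177_lambda_p <- function(half_life_d = 6.647) log(2) / (half_life_d * 24)

#' Decay-correct a measured activity
#'
#' Back-corrects a measured activity to the reference time:
#' `measured * exp(lambda_p * t)`.
#'
#' @param measured measured activity (any unit).
#' @param elapsed_h time since reference, hours (>= 0).
#' @param lambda_p physical decay constant, 1/h.
#' @export
decay_correct <- function(measured, elapsed_h, lambda_p = lu177_lambda_p()) {
  if (any(elapsed_h < 0)) stopf("elapsed time must be >= 0")
  measured * exp(lambda_p * elapsed_h)
}

#' Per-interval cumulated activity
#'
#' Closed form of the cumulated activity in a compartment over the interval
#' \eqn{[T_1, T_2]}:
#' \deqn{\tilde{A} = f A_0 (e^{-\lambda_p T_1} - e^{-\lambda_p T_2})/\lambda_p}
#' with the hours-to-seconds conversion applied, so the result is in Bq s
#' when `A0_Bq` is in Bq. The limit \eqn{\lambda_p \to 0} returns
#' \eqn{f A_0 (T_2 - T_1)}.
#'
#' @param f activity fraction assigned to the compartment (>= 0).
#' @param A0_Bq added activity at the reference time, Bq.
#' @param T1_h,T2_h interval bounds, hours (`T2_h > T1_h >= 0`).
#' @param lambda_p physical decay constant, 1/h.
#' @return cumulated activity, Bq s.
#' @export
cumulated_activity <- function(f, A0_Bq, T1_h, T2_h,
                               lambda_p = lu177_lambda_p()) {
  if (any(f < 0)) stopf("fraction must be >= 0")
  if (any(T2_h <= T1_h) || any(T1_h < 0)) stopf("need T2 > T1 >= 0")
  hours <- if (lambda_p <= 0) T2_h - T1_h
  else (exp(-lambda_p * T1_h) - exp(-lambda_p * T2_h)) / lambda_p
  f * A0_Bq * hours * 3600
}

# robust least squares of A_plat * (1 - exp(-k t)) with analytic gradient
.fit_exp_association <- function(t, y) {
  obj <- function(p) sum((p[1] * (1 - exp(-p[2] * t)) - y)^2)
  a0 <- max(y); k0 <- 1 / max(stats::median(t), 1e-6)
  best <- NULL
  for (k_start in c(k0, 0.5, 1.5, 4)) {
    o <- stats::optim(c(a0, k_start), obj, method = "L-BFGS-B",
                      lower = c(1e-12, 1e-6), control = list(factr = 1e4))
    if (is.null(best) || o$value < best$value) best <- o
  }
  p <- best$par
  # Gauss-Newton covariance from the analytic Jacobian
  J <- cbind(1 - exp(-p[2] * t), p[1] * t * exp(-p[2] * t))
  rss <- best$value
  dof <- max(length(t) - 2, 1)
  cv <- tryCatch(solve(crossprod(J)) * rss / dof, error = function(e) matrix(NA, 2, 2))
  tss <- sum((y - mean(y))^2)
  list(A_plat = p[1], k = p[2],
       A_plat_sd = sqrt(cv[1, 1]), k_sd = sqrt(cv[2, 2]),
       r_squared = 1 - rss / tss, rss = rss)
}

#' Fit the 4-h uptake curves
#'
#' Fits the short-term time-activity curves of one added activity: the
#' membrane-bound fraction as a linear function of incubation time
#' (saturation within the first sampling interval makes the slope small),
#' and the internalized fraction as an exponential association
#' \eqn{A(t) = A_{plat}(1 - e^{-kt})} that plateaus around 2 h. Curves with
#' \eqn{R^2 < 0.95} are flagged.
#'
#' @param time_h timepoints within 0-4 h (>= 4 per compartment).
#' @param membrane,internalized fraction values at `time_h`.
#' @return object of class `time_activity_model` with per-curve parameters,
#'   `r_squared` and `flagged` status.
#' @export
fit_uptake_curves <- function(time_h, membrane, internalized) {
  if (length(time_h) < 4) stopf("need >= 4 timepoints in 0-4 h")
  if (any(!is.finite(c(membrane, internalized))))
    stopf("non-finite fractions in the uptake series")
  mem <- stats::lm(membrane ~ time_h)
  mem_r2 <- if (stats::var(membrane) > 0)
    suppressWarnings(summary(mem)$r.squared) else 1
  int <- .fit_exp_association(time_h, internalized)
  if (!is.finite(int$A_plat))
    stopf("internalized-curve fit failed to converge (rss = %.3g)", int$rss)
  structure(list(
    membrane = list(intercept = unname(stats::coef(mem)[1]),
                    slope = unname(stats::coef(mem)[2]), r_squared = mem_r2),
    internalized = int,
    time_to_95pct_h = log(20) / int$k,
    flagged = int$r_squared < 0.95),
    class = "time_activity_model")
}

#' @export
print.time_activity_model <- function(x, ...) {
  cat(sprintf(paste0("<time_activity_model>\n",
                     "  membrane: f = %.4g + %.4g t (R2 = %.3f)\n",
                     "  internalized: A_plat = %.4g, k = %.3g /h (R2 = %.3f)%s\n"),
              x$membrane$intercept, x$membrane$slope, x$membrane$r_squared,
              x$internalized$A_plat, x$internalized$k, x$internalized$r_squared,
              if (x$flagged) "  [flagged: R2 < 0.95]" else ""))
  invisible(x)
}

#' Fit the daily retention (effective decay) curve
#'
#' Fits an exponential decline \eqn{A(t) = A_1 e^{-\lambda_{eff} t}} to
#' decay-corrected per-cell activities over the follow-up days; the
#' effective decay rate combines excretion and cell death/growth dilution.
#'
#' @param time_h measurement times, hours (>= 3 points).
#' @param activity_per_cell decay-corrected activities per cell.
#' @return list with `lambda_eff` (1/h), `lambda_eff_sd`, `A1`,
#'   `r_squared`, `flagged` (`TRUE` when R^2 < 0.94) and the underlying
#'   log-linear `lm` fit. An increasing series warns but still returns the
#'   fit.
#' @export
fit_daily_retention <- function(time_h, activity_per_cell) {
  if (length(time_h) < 3) stopf("need >= 3 daily points")
  if (any(activity_per_cell <= 0)) stopf("activities must be positive")
  if (activity_per_cell[length(activity_per_cell)] > activity_per_cell[1])
    warnf("activity series increases with time; retention fit is suspect")
  fit <- stats::lm(log(activity_per_cell) ~ time_h)
  sm <- suppressWarnings(summary(fit))  # exact fits trip summary.lm
  r2 <- if (stats::var(log(activity_per_cell)) > 0) sm$r.squared else 1
  lambda <- -unname(stats::coef(fit)[2])
  list(lambda_eff = lambda,
       lambda_eff_sd = unname(sm$coefficients[2, 2]),
       A1 = exp(unname(stats::coef(fit)[1])),
       r_squared = r2, flagged = r2 < 0.94, fit = fit)
}

#' Inverse-distance-weighting extrapolation of activity fractions
#'
#' Interpolates/extrapolates measured fractions across the
#' (added activity, time) plane within one compartment, the method used to
#' obtain the 0.1 and 0.25 MBq/ml curves from the measured 0.5-2.5 MBq/ml
#' ones. Coordinates are log10 added activity and time, each normalised by
#' the grid range; weights are \eqn{d^{-p}}. Queries coinciding with a node
#' return the node value exactly; queries outside the activity range of the
#' grid warn (extrapolation) but still return a value.
#'
#' @param grid data frame with columns `added_activity`, `time_h`,
#'   `fraction` (one compartment).
#' @param activity,time_h query coordinates.
#' @param p IDW power (> 0), default 2.
#' @return interpolated fraction.
#' @export
idw_extrapolate <- function(grid, activity, time_h, p = 2) {
  if (!nrow(grid)) stopf("empty grid")
  if (p <= 0) stopf("IDW power must be > 0")
  la <- log10(grid$added_activity); lq <- log10(activity)
  sa <- max(diff(range(la)), 1e-12)
  st <- max(diff(range(grid$time_h)), 1e-12)
  if (lq < min(la) - 1e-12 || lq > max(la) + 1e-12)
    warnf("query activity %.3g outside the measured range: extrapolating", activity)
  d2 <- ((la - lq) / sa)^2 + ((grid$time_h - time_h) / st)^2
  hit <- d2 < 1e-24
  if (any(hit)) return(mean(grid$fraction[hit]))
  w <- d2^(-p / 2)
  sum(w * grid$fraction) / sum(w)
}

#' Cumulated activities for the whole experiment
#'
#' Builds the per-interval cumulated activities that enter the absorbed
#' dose: the 4-h uptake interval by trapezoidal integration of the measured
#' (decay-corrected) fraction curves multiplied by the physical decay
#' factor, and each follow-up day by the closed form of
#' [cumulated_activity()] with the day's measured fraction. Day 1 spans
#' 4-24 h (20 h), days 2-6 are 24 h each. Cellular compartments (membrane,
#' internalized) are normalised per cell using the day's cell count; counts
#' between measurement days are interpolated exponentially.
#'
#' @param uptake data frame of the 0-4 h curves: columns `time_h`,
#'   `compartment` (`medium`, `membrane`, `internalized`), `fraction`.
#' @param daily data frame of the follow-up days: columns `day` (1-6),
#'   `compartment`, `fraction` (decay-corrected fraction of `A0_Bq` at the
#'   start of each day interval).
#' @param cell_counts data frame with columns `day`, `count` (cells per
#'   well at the end of each day).
#' @param A0_Bq added activity, Bq per well.
#' @param lambda_p physical decay constant, 1/h.
#' @return object of class `cumulated_activities`: data frame `intervals`
#'   with columns `interval`, `T1_h`, `T2_h`, `A_medium` (Bq s per well),
#'   `A_membrane`, `A_internalized` (Bq s per cell).
#' @export
cumulated_activities <- function(uptake, daily, cell_counts, A0_Bq,
                                 lambda_p = lu177_lambda_p()) {
  comp_cols <- c(medium = "A_medium", membrane = "A_membrane",
                 internalized = "A_internalized")
  count_at <- .cell_count_interpolator(cell_counts)

  # 4-h uptake: the fitted time-activity curves (membrane linear,
  # internalized exponential-association, medium interpolated through the
  # measurements) are integrated against A0 * exp(-lambda_p t) on a fine
  # grid; cellular compartments divided by the day-1 cell count
  get_comp <- function(cmp) {
    cur <- uptake[uptake$compartment == cmp, ]
    cur <- cur[order(cur$time_h), ]
    if (nrow(cur) < 4) stopf("need >= 4 uptake points for compartment '%s'", cmp)
    cur
  }
  mem <- get_comp("membrane"); int <- get_comp("internalized")
  med <- get_comp("medium")
  if (!identical(mem$time_h, int$time_h))
    stopf("membrane and internalized uptake series have different timepoints")
  tac <- fit_uptake_curves(mem$time_h, mem$fraction, int$fraction)
  t_hi <- max(mem$time_h)
  tg <- seq(0, t_hi, length.out = 801)
  f_mem <- pmax(tac$membrane$intercept + tac$membrane$slope * tg, 0)
  f_int <- pmax(tac$internalized$A_plat * (1 - exp(-tac$internalized$k * tg)), 0)
  f_med <- pmax(stats::splinefun(med$time_h, med$fraction,
                                 method = "natural")(tg), 0)
  decay <- A0_Bq * exp(-lambda_p * tg) * 3600
  res <- data.frame(interval = "uptake", T1_h = 0, T2_h = t_hi,
                    A_medium = .trapz(tg, f_med * decay),
                    A_membrane = .trapz(tg, f_mem * decay) / count_at(1),
                    A_internalized = .trapz(tg, f_int * decay) / count_at(1),
                    stringsAsFactors = FALSE)

  for (d in sort(unique(daily$day))) {
    T1 <- if (d == 1) 4 else 24 * (d - 1)
    T2 <- 24 * d
    row <- data.frame(interval = paste0("day", d), T1_h = T1, T2_h = T2,
                      A_medium = 0, A_membrane = NA_real_,
                      A_internalized = NA_real_, stringsAsFactors = FALSE)
    for (cmp in names(comp_cols)) {
      f <- daily$fraction[daily$day == d & daily$compartment == cmp]
      if (!length(f)) {
        if (cmp == "medium") next
        stopf("missing daily fraction for day %d, compartment '%s'", d, cmp)
      }
      A_bqs <- cumulated_activity(mean(f), A0_Bq, T1, T2, lambda_p)
      if (cmp != "medium") A_bqs <- A_bqs / count_at(d)
      row[[comp_cols[[cmp]]]] <- A_bqs
    }
    res <- rbind(res, row)
  }
  structure(list(intervals = res, A0_Bq = A0_Bq, lambda_p = lambda_p),
            class = "cumulated_activities")
}

# exponential interpolation of cell counts between measured days
.cell_count_interpolator <- function(cell_counts) {
  cc <- cell_counts[order(cell_counts$day), ]
  if (any(cc$count <= 0)) stopf("cell counts must be positive")
  function(day) {
    exp(stats::approx(cc$day, log(cc$count), xout = day, rule = 2)$y)
  }
}

#' @export
print.cumulated_activities <- function(x, ...) {
  cat(sprintf("<cumulated_activities> A0 = %.3g Bq, lambda_p = %.4g /h\n",
              x$A0_Bq, x$lambda_p))
  print(x$intervals, row.names = FALSE)
  invisible(x)
}
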