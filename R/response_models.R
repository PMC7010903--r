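# Clonogenic dose-response: survival fractions from colony counts, linear
# and linear-quadratic model fits, AIC model selection.

#' Survival fraction from colony counts
#'
#' \eqn{SF = (colonies/seeded)/PE} with the plating efficiency PE from
#' untreated controls; the SEM is taken over replicates.
#'
#' @param colonies colony counts per replicate (>= 0).
#' @param seeded cells seeded per replicate (> 0).
#' @param plating_efficiency PE in (0, 1].
#' @return list with `sf` (mean), `sem`, `per_replicate`, and `flagged_zero`
#'   (`TRUE` when SF = 0, which must be excluded from log-domain fits).
#' @export
survival_from_colonies <- function(colonies, seeded, plating_efficiency) {
  if (any(seeded <= 0)) stopf("seeded cell number must be > 0")
  if (plating_efficiency <= 0 || plating_efficiency > 1)
    stopf("plating efficiency must be in (0, 1]")
  if (any(colonies < 0)) stopf("colony counts must be >= 0")
  sf_rep <- (colonies / seeded) / plating_efficiency
  n <- length(sf_rep)
  list(sf = mean(sf_rep),
       sem = if (n > 1) stats::sd(sf_rep) / sqrt(n) else NA_real_,
       per_replicate = sf_rep,
       flagged_zero = mean(sf_rep) == 0)
}

# least squares of SF = exp(-a D - b D^2) with a, b >= 0 (b fixed at 0 for
# the linear model); analytic Jacobian for the covariance.
.fit_sf <- function(dose, sf, quadratic, log_domain = FALSE) {
  yfun <- if (log_domain) function(m) log(pmax(m, 1e-300)) else identity
  y <- yfun(sf)
  model <- function(p) exp(-p[1] * dose - if (quadratic) p[2] * dose^2 else 0)
  obj <- function(p) sum((yfun(model(p)) - y)^2)
  # starting values from a log-linear regression
  pos <- sf > 0
  lf <- stats::lm(log(sf[pos]) ~ 0 + dose[pos] + I(dose[pos]^2))
  st <- pmax(unname(-stats::coef(lf)), 1e-6)
  st[!is.finite(st)] <- 1e-6
  if (!quadratic) {
    o <- stats::optimize(function(a) obj(a), c(0, max(st[1] * 10, 5)),
                         tol = 1e-10)
    p <- c(o$minimum, 0); rss <- o$objective; k <- 1
  } else {
    o <- stats::optim(st, obj, method = "L-BFGS-B", lower = c(0, 0),
                      control = list(factr = 1e3))
    p <- o$par; rss <- o$value; k <- 2
  }
  m <- model(p)
  J <- cbind(-dose * (if (log_domain) 1 else m),
             if (quadratic) -dose^2 * (if (log_domain) 1 else m))
  dof <- max(length(dose) - k, 1)
  cv <- tryCatch(solve(crossprod(J)) * rss / dof,
                 error = function(e) matrix(NA, k, k))
  list(alpha = p[1], beta = p[2], alpha_sd = sqrt(cv[1, 1]),
       beta_sd = if (quadratic) sqrt(cv[2, 2]) else 0,
       rss = rss, fitted = m, k = k)
}

#' Fit a dose-response model to clonogenic survival data
#'
#' Least-squares fit of \eqn{SF = e^{-\alpha D - \beta D^2}} (model
#' `"LQ"`) or \eqn{SF = e^{-\alpha D}} (model `"linear"`), unweighted and on
#' the survival-fraction scale by default (`log_domain = TRUE` fits on
#' \eqn{\log SF} instead). Nonnegativity \eqn{\alpha, \beta \ge 0} is
#' enforced. The goodness of fit is Pearson's \eqn{R^2}, reported both on
#' SF and on log SF; the AIC is \eqn{n \ln(RSS/n) + 2k}.
#'
#' @param dose_Gy absorbed doses, Gy.
#' @param sf survival fractions in (0, 1] (a zero SF is dropped from
#'   log-domain fits).
#' @param model `"linear"` or `"LQ"`.
#' @param log_domain fit on log SF instead of SF.
#' @return object of class `dose_response_fit` with `alpha`, `beta` (1/Gy,
#'   1/Gy^2) and SDs, `alpha_over_beta`, `r_squared`, `r_squared_log`,
#'   `aic`, `n`.
#' @export
fit_dose_response <- function(dose_Gy, sf, model = c("LQ", "linear"),
                              log_domain = FALSE) {
  model <- match.arg(model)
  quadratic <- model == "LQ"
  keep <- rep(TRUE, length(sf))
  if (log_domain) keep <- sf > 0
  if (sum(keep) < (quadratic + 1) + 1)
    stopf("need at least %d dose points for the %s model", quadratic + 2, model)
  d <- dose_Gy[keep]; s <- sf[keep]
  f <- .fit_sf(d, s, quadratic, log_domain)
  if (!is.finite(f$rss))
    stopf("dose-response fit failed to converge (model %s)", model)
  n <- length(d)
  r2 <- function(obs, fit) {
    tss <- sum((obs - mean(obs))^2)
    if (tss == 0) 1 else 1 - sum((obs - fit)^2) / tss
  }
  pos <- s > 0
  structure(list(
    model = model, alpha = f$alpha, beta = f$beta,
    alpha_sd = f$alpha_sd, beta_sd = f$beta_sd,
    alpha_over_beta = if (f$beta > 0) f$alpha / f$beta else Inf,
    r_squared = r2(s, f$fitted),
    r_squared_log = r2(log(s[pos]), log(f$fitted[pos])),
    rss = f$rss, aic = n * log(f$rss / n) + 2 * f$k,
    n = n, k = f$k, log_domain = log_domain,
    dose_Gy = d, sf = s, fitted = f$fitted),
    class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf(paste0("<dose_response_fit> %s: alpha = %.3g +/- %.2g /Gy",
                     "%s, R2 = %.3f, AIC = %.2f (n = %d)\n"),
              x$model, x$alpha, x$alpha_sd,
              if (x$model == "LQ")
                sprintf(", beta = %.3g +/- %.2g /Gy^2 (a/b = %.3g Gy)",
                        x$beta, x$beta_sd, x$alpha_over_beta) else "",
              x$r_squared, x$aic, x$n))
  invisible(x)
}

#' AIC model selection between dose-response fits
#'
#' Chooses the fit with the lowest AIC; on a tie (|dAIC| < `tie_tol`) the
#' model with fewer parameters wins. The selection is classified as the
#' linear regime when the linear model wins or the fitted
#' \eqn{\alpha/\beta > 100} Gy.
#'
#' @param fits list of `dose_response_fit` objects on identical data.
#' @param tie_tol AIC difference treated as a tie.
#' @return list with `chosen` (the winning fit), `delta_aic`, `tie`,
#'   `linear_regime`.
#' @export
model_select_aic <- function(fits, tie_tol = 1e-8) {
  if (!length(fits)) stopf("no fits supplied")
  ns <- vapply(fits, function(f) f$n, 0)
  if (length(unique(ns)) != 1) stopf("fits are not on identical data")
  aics <- vapply(fits, function(f) f$aic, 0)
  ks <- vapply(fits, function(f) f$k, 0)
  tie <- abs(diff(range(aics))) < tie_tol
  idx <- if (tie) which.min(ks) else which.min(aics)
  chosen <- fits[[idx]]
  list(chosen = chosen,
       delta_aic = aics - min(aics),
       tie = tie,
       linear_regime = chosen$model == "linear" || chosen$alpha_over_beta > 100)
}
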