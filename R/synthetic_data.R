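# Synthetic-data generator: measurement tables with the statistical
# structure of the gamma-counter uptake assays (added activities
# 0.1-2.5 MBq/ml, 15-min resolution during the 4-h uptake, daily points
# over 6 follow-up days, 2 experiments x triplicate, lognormal noise),
# survival datasets from known dose-response truth, and programmatic
# polygonal-mesh cells. Every dataset carries its analytic ground truth.

#' Synthetic experiment configuration
#'
#' Defaults emulate the study conditions: added activities 0.1-2.5 MBq/ml
#' in 1 ml medium; receptor-limited internalization plateauing around 2 h
#' (k = 1.5 /h, time to 95% plateau ~2 h) with a saturable plateau fraction
#' \eqn{f(a) = f_{ref}(a_{ref} + K)/(a + K)} (0.8% of the added activity at
#' 2.5 MBq/ml, rising towards lower activities), which reproduces the
#' observed scale of absorbed doses (~0.2-2 Gy over the experiment) and the
#' near-equal doses of intermediate activities; membrane binding saturating
#' within the first sampling interval (~0.1% with a small residual slope);
#' effective decay rate 0.024 /h during follow-up; doubling time 35 h
#' (observed range 27-44 h); measurement noise as multiplicative lognormal
#' with CVs of 15% for activity fractions (range 5-33%), 14.5% for cell
#' counts (11-18%) and 2% for added activities (1-3%).
#'
#' @param activities added activities, MBq/ml.
#' @param volume_ml medium volume per well.
#' @param f_plateau_ref internalized plateau fraction at the reference
#'   (highest) added activity.
#' @param K_sat saturation constant of the uptake fraction, MBq/ml.
#' @param k_uptake exponential-association rate, 1/h.
#' @param f_membrane_ref membrane-bound fraction at the reference activity.
#' @param membrane_slope relative slope of the membrane fraction, 1/h.
#' @param lambda_eff effective decay rate during follow-up, 1/h.
#' @param lambda_p physical decay constant, 1/h.
#' @param Td_h doubling time, h.
#' @param n0_cells cells per well at treatment start.
#' @param cv_fractions,cv_counts,cv_activity noise CVs.
#' @param alpha_true linear dose-response coefficient truth, 1/Gy.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(activities = c(0.1, 0.25, 0.5, 1, 2.5),
                             volume_ml = 1,
                             f_plateau_ref = 0.008, K_sat = 1,
                             k_uptake = 1.5,
                             f_membrane_ref = 0.001, membrane_slope = 0.01,
                             lambda_eff = 0.024,
                             lambda_p = lu177_lambda_p(),
                             Td_h = 35, n0_cells = 1e5,
                             cv_fractions = 0.15, cv_counts = 0.145,
                             cv_activity = 0.02,
                             alpha_true = 0.33) {
  cfg <- as.list(environment())
  cfg$a_ref <- max(cfg$activities)
  stopifnot(all(unlist(cfg[c("k_uptake", "lambda_eff", "lambda_p", "Td_h",
                             "K_sat")]) > 0))
  if (cv_fractions < 0.05 || cv_fractions > 0.33)
    stopf("cv_fractions outside the observed 5-33%% range")
  if (cv_counts < 0.11 || cv_counts > 0.18)
    stopf("cv_counts outside the observed 11-18%% range")
  if (cv_activity < 0.01 || cv_activity > 0.03)
    stopf("cv_activity outside the observed 1-3%% range")
  structure(cfg, class = "synthetic_config")
}

# multiplicative lognormal noise with unit mean and given CV
.lnoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

# saturable plateau fractions at added activity a
.sat_fraction <- function(cfg, a, ref)
  ref * (cfg$a_ref + cfg$K_sat) / (a + cfg$K_sat)

# true compartment fractions of added activity (decay-corrected), 0-4 h
.uptake_truth <- function(cfg, t_h, a) {
  f_int <- .sat_fraction(cfg, a, cfg$f_plateau_ref) *
    (1 - exp(-cfg$k_uptake * t_h))
  f_mem <- .sat_fraction(cfg, a, cfg$f_membrane_ref) *
    (1 + cfg$membrane_slope * t_h)
  data.frame(time_h = t_h, medium = 1 - f_int - f_mem,
             membrane = f_mem, internalized = f_int)
}

# true per-well cellular fractions at follow-up time t (hours since t=0);
# cellular pools decline with lambda_eff after the 4-h wash, the excreted
# part accumulates in the (renewed) medium
.daily_truth <- function(cfg, t_h, a) {
  end <- .uptake_truth(cfg, 4, a)
  ret <- exp(-cfg$lambda_eff * (t_h - 4))
  data.frame(time_h = t_h,
             membrane = end$membrane * ret,
             internalized = end$internalized * ret,
             medium = (end$membrane + end$internalized) * (1 - ret))
}

.cell_count_truth <- function(cfg, day)
  cfg$n0_cells * 2^(24 * (day - 1) / cfg$Td_h)

#' Generate a synthetic uptake experiment
#'
#' Produces the measurement tables of one full uptake + follow-up
#' experiment for every configured added activity: 15-min-resolution
#' fraction measurements during the 4-h uptake, daily measurements on
#' days 1-6, and per-day cell counts; 2 independent experiments x
#' triplicate with multiplicative lognormal noise. Compartment conservation
#' (fractions summing to 1) holds exactly before noise. The attached
#' `truth` record holds the generating parameters and the analytic
#' per-interval cumulated activities.
#'
#' @param config a `synthetic_config`.
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return list with data frames `uptake` (columns `experiment`,
#'   `replicate`, `added_activity`, `time_h`, `compartment`, `fraction`),
#'   `daily` (idem with `day`), `cell_counts` (`day`, `count`), and `truth`.
#' @export
generate_uptake_dataset <- function(config = synthetic_config(), seed = 1) {
  cfg <- config
  with_seed(seed, {
    t_up <- seq(0, 4, by = 0.25)  # t = 0 is the known pre-incubation state
    days <- 1:6
    t_day <- ifelse(days == 1, 4, 24 * (days - 1))  # interval-start times
    reps <- expand.grid(experiment = 1:2, replicate = 1:3)
    up_rows <- list(); day_rows <- list()
    for (a in cfg$activities) {
      tru_up <- .uptake_truth(cfg, t_up, a)
      tru_day <- .daily_truth(cfg, t_day, a)
      for (r in seq_len(nrow(reps))) {
        for (cmp in c("medium", "membrane", "internalized")) {
          up_rows[[length(up_rows) + 1]] <- data.frame(
            experiment = reps$experiment[r], replicate = reps$replicate[r],
            added_activity = a, time_h = t_up, compartment = cmp,
            fraction = tru_up[[cmp]] * .lnoise(length(t_up), cfg$cv_fractions),
            stringsAsFactors = FALSE)
          day_rows[[length(day_rows) + 1]] <- data.frame(
            experiment = reps$experiment[r], replicate = reps$replicate[r],
            added_activity = a, day = days, compartment = cmp,
            fraction = tru_day[[cmp]] * .lnoise(length(days), cfg$cv_fractions),
            stringsAsFactors = FALSE)
        }
      }
    }
    counts <- data.frame(
      day = days,
      count = .cell_count_truth(cfg, days) * .lnoise(length(days), cfg$cv_counts))

    truth <- list(config = cfg,
                  cumulated = lapply(stats::setNames(cfg$activities,
                                                     paste0("a", cfg$activities)),
                                     function(a) .true_cumulated(cfg, a)))
    list(uptake = do.call(rbind, up_rows),
         daily = do.call(rbind, day_rows),
         cell_counts = counts, truth = truth)
  })
}

# analytic ground-truth cumulated activities (same interval convention as
# cumulated_activities(); uptake interval by fine-grained quadrature)
.true_cumulated <- function(cfg, activity_MBq_ml) {
  A0 <- activity_MBq_ml * 1e6 * cfg$volume_ml
  tg <- seq(0, 4, length.out = 4001)
  tru <- .uptake_truth(cfg, tg, activity_MBq_ml)
  n1 <- .cell_count_truth(cfg, 1)
  intr <- function(f) .trapz(tg, f * A0 * exp(-cfg$lambda_p * tg)) * 3600
  res <- data.frame(interval = "uptake", T1_h = 0, T2_h = 4,
                    A_medium = intr(tru$medium),
                    A_membrane = intr(tru$membrane) / n1,
                    A_internalized = intr(tru$internalized) / n1,
                    stringsAsFactors = FALSE)
  for (d in 1:6) {
    T1 <- if (d == 1) 4 else 24 * (d - 1); T2 <- 24 * d
    td <- if (d == 1) 4 else 24 * (d - 1)
    f <- .daily_truth(cfg, td, activity_MBq_ml)
    nd <- .cell_count_truth(cfg, d)
    res <- rbind(res, data.frame(
      interval = paste0("day", d), T1_h = T1, T2_h = T2,
      A_medium = 0,
      A_membrane = cumulated_activity(f$membrane, A0, T1, T2, cfg$lambda_p) / nd,
      A_internalized = cumulated_activity(f$internalized, A0, T1, T2,
                                          cfg$lambda_p) / nd,
      stringsAsFactors = FALSE))
  }
  structure(list(intervals = res, A0_Bq = A0, lambda_p = cfg$lambda_p),
            class = "cumulated_activities")
}

#' Run the kinetics pipeline on a (synthetic or measured) dataset
#'
#' Averages replicates, assembles per-interval cumulated activities for one
#' added activity, and returns the `cumulated_activities` object the dose
#' assembly consumes.
#'
#' @param dataset list with `uptake`, `daily`, `cell_counts` as produced by
#'   [generate_uptake_dataset()] (or read from CSVs with the same columns).
#' @param activity added activity to extract, MBq/ml.
#' @param volume_ml medium volume per well.
#' @param lambda_p physical decay constant, 1/h.
#' @return a `cumulated_activities` object.
#' @export
pipeline_cumulated <- function(dataset, activity, volume_ml = 1,
                               lambda_p = lu177_lambda_p()) {
  up <- dataset$uptake[dataset$uptake$added_activity == activity, ]
  dy <- dataset$daily[dataset$daily$added_activity == activity, ]
  if (!nrow(up)) stopf("no uptake rows for activity %g", activity)
  up_m <- stats::aggregate(fraction ~ time_h + compartment, up, mean)
  dy_m <- stats::aggregate(fraction ~ day + compartment, dy, mean)
  cumulated_activities(up_m, dy_m, dataset$cell_counts,
                       A0_Bq = activity * 1e6 * volume_ml, lambda_p = lambda_p)
}

#' Generate a synthetic clonogenic survival dataset
#'
#' Survival fractions from the linear (or linear-quadratic) truth
#' \eqn{SF = e^{-\alpha D - \beta D^2}}, perturbed with multiplicative
#' lognormal noise, optionally realised as binomial colony counts
#' (`seeded * SF * PE` successes).
#'
#' @param alpha_true,beta_true dose-response truth (1/Gy, 1/Gy^2).
#' @param doses_Gy absorbed doses.
#' @param replicates replicates per dose.
#' @param noise_cv relative SD of the multiplicative noise.
#' @param binomial draw colony counts instead of continuous noise?
#' @param seeded,plating_efficiency colony-assay parameters (binomial mode).
#' @param seed integer seed.
#' @return data frame (`dose_Gy`, `replicate`, `sf`, and `colonies` in
#'   binomial mode) with the truth in `attr(,"truth")`.
#' @export
generate_survival_dataset <- function(alpha_true, doses_Gy, replicates = 3,
                                      noise_cv = 0.1, beta_true = 0,
                                      binomial = FALSE, seeded = 300,
                                      plating_efficiency = 0.5, seed = 1) {
  if (alpha_true <= 0) stopf("alpha must be > 0")
  with_seed(seed, {
    grid <- expand.grid(dose_Gy = doses_Gy, replicate = seq_len(replicates))
    sf_true <- exp(-alpha_true * grid$dose_Gy - beta_true * grid$dose_Gy^2)
    if (binomial) {
      col <- stats::rbinom(nrow(grid), seeded,
                           pmin(sf_true * plating_efficiency, 1))
      grid$colonies <- col
      grid$sf <- (col / seeded) / plating_efficiency
    } else {
      grid$sf <- sf_true * .lnoise(nrow(grid), noise_cv)
    }
    attr(grid, "truth") <- list(alpha = alpha_true, beta = beta_true,
                                seeded = seeded, pe = plating_efficiency)
    grid
  })
}

# ---- programmatic mesh cells ------------------------------------------------

# subdivided icosahedron on the unit sphere
.icosphere <- function(subdiv = 2) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    edge_mid <- new.env()
    mid <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      got <- edge_mid[[key]]
      if (!is.null(got)) return(got)
      m <- v[i, ] + v[j, ]
      m <- m / sqrt(sum(m^2))
      v <<- rbind(v, m)
      edge_mid[[key]] <- nrow(v)
      nrow(v)
    }
    nf <- matrix(0L, 0, 3)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; c_ <- f[k, 3]
      ab <- mid(a, b); bc <- mid(b, c_); ca <- mid(c_, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(c_, ca, bc), c(ab, bc, ca))
    }
    f <- nf
  }
  structure(list(vertices = v, faces = f), class = "tri_mesh")
}

# closed torus mesh (axis z), ring radius R, tube radius r, centred at ctr
.torus_mesh <- function(R, r, ctr = c(0, 0, 0), nu = 28, nv = 14) {
  iu <- seq_len(nu) - 1; iv <- seq_len(nv) - 1
  g <- expand.grid(u = iu, v = iv)
  phi <- 2 * pi * g$u / nu; th <- 2 * pi * g$v / nv
  rho <- R + r * cos(th)
  v <- cbind(ctr[1] + rho * cos(phi), ctr[2] + rho * sin(phi),
             ctr[3] + r * sin(th))
  idx <- function(u, vv) (vv %% nv) * nu + (u %% nu) + 1
  f <- matrix(0L, 0, 3)
  for (u in iu) for (vv in iv) {
    a <- idx(u, vv); b <- idx(u + 1, vv); c_ <- idx(u + 1, vv + 1); d <- idx(u, vv + 1)
    f <- rbind(f, c(a, b, c_), c(a, c_, d))
  }
  mesh_orient(structure(list(vertices = v, faces = f), class = "tri_mesh"))
}

# smooth low-order angular perturbation field on unit directions
.smooth_field <- function(dirs, seed_coefs) {
  a <- seed_coefs
  s <- a[1] * dirs[, 1] * dirs[, 3] + a[2] * dirs[, 2] * dirs[, 3] +
    a[3] * (dirs[, 1]^2 - dirs[, 2]^2) + a[4] * dirs[, 1] * dirs[, 2] +
    a[5] * dirs[, 3]^2
  s - mean(s)
}

#' Generate a synthetic polygonal-mesh cell
#'
#' Builds watertight triangle meshes emulating an imaged adherent cell:
#' smoothly perturbed flattened ellipsoids for the cell surface and
#' nucleus, plus a curved-tube (torus) Golgi beside the nucleus, each
#' rescaled to hit its target volume within 1%. Containment (nucleus and
#' Golgi strictly inside the cell, Golgi disjoint from the nucleus) is
#' verified; on violation the perturbation amplitude is halved and the
#' surfaces regenerated (error after 10 attempts).
#'
#' @param v_cell,v_nucleus,v_golgi target volumes, um^3.
#' @param d_gn minimum Golgi-nucleus distance, um.
#' @param amplitude relative perturbation amplitude (0 = exact ellipsoids).
#' @param seed integer seed; fixed seed gives identical meshes.
#' @param subdiv icosphere subdivision level.
#' @param dir optional directory: when given, writes
#'   `cytoplasm.obj` / `nucleus.obj` / `golgi.obj` there.
#' @return the assembled `cell_model` (invisible file paths in
#'   `attr(,"files")` when `dir` is given).
#' @export
generate_mesh_cell <- function(v_cell = 3546, v_nucleus = 1061,
                               v_golgi = 60, d_gn = 1,
                               amplitude = 0.08, seed = 1, subdiv = 2,
                               dir = NULL) {
  if (v_nucleus >= v_cell) stopf("nucleus volume must be < cell volume")
  base <- .icosphere(subdiv)
  with_seed(seed, {
    for (attempt in seq_len(10)) {
      amp <- amplitude / 2^(attempt - 1)
      make_blob <- function(semi, amp) {
        co <- stats::runif(5, -1, 1)
        radial <- 1 + amp * .smooth_field(base$vertices, co)
        v <- sweep(base$vertices * radial, 2, semi, "*")
        structure(list(vertices = v, faces = base$faces), class = "tri_mesh")
      }
      rescale_to <- function(m, target) {
        k <- (target / mesh_volume(m))^(1 / 3)
        m$vertices <- m$vertices * k
        m
      }
      # flattened adherent-cell aspect; heights ~ footprint/4
      cy <- rescale_to(make_blob(c(1, 0.92, 0.33), amp), v_cell)
      nu <- rescale_to(make_blob(c(1, 0.95, 0.30), amp / 2), v_nucleus)
      # centre nucleus inside the cell, slightly below mid-height
      nu$vertices <- sweep(nu$vertices, 2, c(0, 0, -0.05 * diff(range(cy$vertices[, 3]))), "+")
      a_n <- max(nu$vertices[, 1])
      r_tube <- sqrt(v_golgi / (2 * pi^2 * (a_n + d_gn)))
      ring <- a_n + d_gn + r_tube
      go <- .torus_mesh(ring, r_tube, ctr = c(0, 0, 0))
      go <- rescale_to(go, v_golgi)
      ok <- tryCatch({
        cell <- load_mesh_cell(cy, nu, go)
        cell
      }, error = function(e) NULL)
      if (!is.null(ok)) {
        vol_ok <- abs(ok$volumes$cell / v_cell - 1) < 0.01 &&
          abs(ok$volumes$nucleus / v_nucleus - 1) < 0.01 &&
          abs(ok$volumes$golgi / v_golgi - 1) < 0.01
        if (vol_ok) {
          if (!is.null(dir)) {
            dir.create(dir, recursive = TRUE, showWarnings = FALSE)
            files <- file.path(dir, c("cytoplasm.obj", "nucleus.obj", "golgi.obj"))
            write_mesh(cy, files[1]); write_mesh(nu, files[2])
            write_mesh(go, files[3])
            attr(ok, "files") <- files
          }
          return(ok)
        }
      }
    }
    stopf("could not generate a valid mesh cell after 10 attempts")
  })
}
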