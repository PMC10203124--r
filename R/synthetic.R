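# Synthetic threshold-measurement studies and power-ramp experiments.
#
# The generator emulates the design of the real measurement campaign: a set
# of grid designs (patterns x meshes) per film material, each yielding one
# observed maximum illumination power density. Observations are the forward
# model's threshold with multiplicative log-normal noise, censored from
# above at the instrument ceiling (690 W/cm^2 by default: thresholds beyond
# it are recorded as "gt" at the ceiling, exactly like the real formvar and
# silicon-monoxide rows). Every draw comes from a counter-based substream
# of the study seed, so adding or reordering rows never changes other
# rows' draws.

#' Specify a synthetic threshold-measurement study
#'
#' @param true_alpha Named numeric vector of true effective film parameters
#'   per material, K um^-2 (W/cm^2)^-1. Defaults are the values calibrated
#'   from the packaged measurement table (CFlat carbon 3.37e-3, Quantifoil
#'   carbon 3.89e-3, gold film 6.75e-4).
#' @param designs Data frame of grid designs with columns `grid_id`,
#'   `film_material`, `hole_diameter_um`, `hole_spacing_um`, `mesh`,
#'   `square_size_um`, `bar_metal`. Defaults to [default_study_designs()]
#'   over the materials of `true_alpha`.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   measurement noise (>= 0). There is no empirical replicate data to set
#'   this from; it is a simulation knob.
#' @param censor_limit Instrument ceiling in W/cm^2 (default 690).
#' @param replicates Number of replicate datasets for
#'   [recovery_experiment()].
#' @param seed Integer study seed; identical seeds give identical datasets.
#' @param params A [thermal_params()].
#' @return An object of class `synthetic_study_spec`.
#' @export
synthetic_study_spec <- function(true_alpha = c(carbon_cflat = 3.37e-3,
                                                carbon_quantifoil = 3.89e-3,
                                                gold_film = 6.75e-4),
                                 designs = default_study_designs(names(true_alpha)),
                                 noise_cv = 0.05, censor_limit = 690,
                                 replicates = 1L, seed = 1L,
                                 params = thermal_params()) {
  stopifnot(is.numeric(true_alpha), !is.null(names(true_alpha)),
            all(true_alpha > 0), noise_cv >= 0, censor_limit > 0,
            replicates >= 1)
  stopifnot(all(designs$film_material %in% names(true_alpha)))
  out <- list(true_alpha = true_alpha, designs = designs,
              noise_cv = noise_cv, censor_limit = censor_limit,
              replicates = as.integer(replicates), seed = as.integer(seed),
              params = params)
  class(out) <- "synthetic_study_spec"
  out
}

#' Default grid designs for a synthetic study
#'
#' Six designs per material: the three commercial hole patterns (2/1,
#' 1.2/1.3, 1/4) crossed with 300 and 400 mesh — the pattern and mesh range
#' of the real measurement campaign.
#'
#' @param materials Character vector of material keys.
#' @param patterns List of `c(diameter, spacing)` hole patterns.
#' @param meshes Mesh numbers.
#' @return A designs data frame.
#' @export
default_study_designs <- function(materials,
                                  patterns = list(c(2, 1), c(1.2, 1.3),
                                                  c(1, 4)),
                                  meshes = c(300, 400)) {
  rows <- list()
  for (m in materials) for (p in patterns) for (mesh in meshes) {
    rows[[length(rows) + 1L]] <- data.frame(
      grid_id = sprintf("%s_%g-%g_%d", m, p[1], p[2], mesh),
      film_material = m, hole_diameter_um = p[1], hole_spacing_um = p[2],
      mesh = mesh, square_size_um = square_size_from_mesh(mesh),
      bar_metal = "copper", stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

# Counter-based substream: a deterministic 32-bit seed per (study seed,
# replicate, row), so draws are tied to rows rather than to row order.
substream_seed <- function(seed, replicate, counter) {
  ((as.double(seed) * 2654435761 + replicate * 97003 + counter * 7919)
   %% 2147483647) + 1
}

#' Simulate one threshold-measurement dataset
#'
#' For each design, the true threshold is the closed-form
#' `P_max = 8 (Tmax - T0) / (alpha eta_c L^2)` and the observation is
#' `P_obs = P_max exp(eps)` with `eps ~ N(0, sigma^2)`,
#' `sigma^2 = log(1 + cv^2)` so the multiplicative noise has the requested
#' coefficient of variation. Observations beyond the instrument ceiling
#' are recorded as censored (`censor = "gt"`) at the ceiling. The output
#' uses the same CSV dialect as the packaged measurement table, so
#' synthetic and real data are interchangeable everywhere downstream.
#'
#' @param spec A [synthetic_study_spec()].
#' @param replicate Replicate index (selects the noise substream).
#' @return Measurements data frame with `true_pmax` and the observed
#'   (possibly censored) `measured_pmax_W_cm2`.
#' @export
simulate_threshold_dataset <- function(spec, replicate = 1L) {
  stopifnot(inherits(spec, "synthetic_study_spec"))
  d <- spec$designs
  n <- nrow(d)
  eta <- vapply(seq_len(n), function(i)
    carbon_area_fraction(catalogue_pattern(d[i, ])), numeric(1))
  alpha <- spec$true_alpha[d$film_material]
  p_true <- 8 * delta_T(spec$params) / (alpha * eta * d$square_size_um^2)
  sigma <- sqrt(log(1 + spec$noise_cv^2))
  p_obs <- p_true
  if (sigma > 0) {
    old <- rng_state_get()
    on.exit(rng_state_set(old), add = TRUE)
    for (i in seq_len(n)) {
      set.seed(substream_seed(spec$seed, replicate, i))
      p_obs[i] <- p_true[i] * exp(stats::rnorm(1, 0, sigma))
    }
  }
  censored <- p_obs > spec$censor_limit
  data.frame(
    grid_id = d$grid_id, film_material = d$film_material,
    hole_diameter_um = d$hole_diameter_um,
    hole_spacing_um = d$hole_spacing_um, mesh = d$mesh,
    square_size_um = d$square_size_um, bar_metal = d$bar_metal,
    eta_c = eta, true_pmax = unname(p_true),
    measured_pmax_W_cm2 = unname(ifelse(censored, spec$censor_limit, p_obs)),
    censor = ifelse(censored, "gt", "none"),
    stringsAsFactors = FALSE)
}

# Save/restore the global RNG state so simulation functions do not disturb
# the caller's stream.
rng_state_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
rng_state_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Simulate a stepwise power-ramp experiment
#'
#' Deterministic chain through the heat model and the damage rules for one
#' grid: for each power in the schedule, the steady-state peak temperature
#' at that power, plus the cumulative damage state and half-width.
#' Devitrification is irreversible, so both damage columns are governed by
#' the running maximum of the applied power, not the instantaneous value.
#'
#' @param design One-row designs data frame or a [grid_spec()].
#' @param true_alpha Effective film parameter of the material.
#' @param powers Numeric vector of illumination power densities, W/cm^2,
#'   applied in order.
#' @param params A [thermal_params()].
#' @return Data frame with `step`, `P`, `peak_T`, `state`, `half_width`.
#' @export
simulate_power_ramp <- function(design, true_alpha, powers,
                                params = thermal_params()) {
  stopifnot(length(powers) >= 1, all(powers > 0), true_alpha > 0)
  if (inherits(design, "grid_spec")) {
    eta <- carbon_area_fraction(design$film_pattern)
    L <- design$square_size
  } else {
    eta <- carbon_area_fraction(catalogue_pattern(design))
    L <- design$square_size_um
  }
  p_thr <- max_power_density(true_alpha, L, params$T0, params$Tmax, eta)
  a_eff <- true_alpha * eta   # area-homogenized absorption
  # devitrification is irreversible, so the damage record at each step is
  # governed by the largest power applied so far
  p_run <- cummax(powers)
  rows <- lapply(seq_along(powers), function(k) {
    field_run <- steady_1d(p_run[k], a_eff, L, params$T0, n_points = 513)
    assess <- classify_state(field_run, params$Tmax)
    data.frame(step = k, P = powers[k],
               peak_T = peak_temperature(powers[k], a_eff, L, params$T0),
               state = assess$state,
               half_width = damage_half_width(p_run[k], p_thr, L))
  })
  do.call(rbind, rows)
}

#' Parameter-recovery experiment for the calibration
#'
#' Simulates `spec$replicates` independent threshold datasets, fits alpha
#' per material on each, and summarises the recovery error: per-material
#' relative bias, relative RMSE and the median absolute relative error of
#' the estimates across replicates. With zero noise the recovery is exact;
#' this is the end-to-end validation surface for the calibration stage.
#'
#' @param spec A [synthetic_study_spec()].
#' @return List with `per_material` (summary data frame) and `estimates`
#'   (replicate x material matrix of alpha-hat).
#' @export
recovery_experiment <- function(spec) {
  stopifnot(inherits(spec, "synthetic_study_spec"))
  mats <- names(spec$true_alpha)
  est <- matrix(NA_real_, spec$replicates, length(mats),
                dimnames = list(NULL, mats))
  for (r in seq_len(spec$replicates)) {
    ds <- simulate_threshold_dataset(spec, replicate = r)
    cal <- fit_alpha(ds, params = spec$params)
    idx <- match(mats, cal$materials$film_material)
    est[r, ] <- cal$materials$alpha[idx]
  }
  rel_err <- sweep(est, 2, spec$true_alpha[mats], "/") - 1
  per_material <- data.frame(
    film_material = mats,
    true_alpha = unname(spec$true_alpha[mats]),
    mean_alpha_hat = colMeans(est, na.rm = TRUE),
    rel_bias = colMeans(rel_err, na.rm = TRUE),
    rel_rmse = sqrt(colMeans(rel_err^2, na.rm = TRUE)),
    median_abs_rel_err = apply(abs(rel_err), 2, stats::median, na.rm = TRUE),
    n_failed = colSums(is.na(est)),
    stringsAsFactors = FALSE)
  rownames(per_material) <- NULL
  list(per_material = per_material, estimates = est)
}
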