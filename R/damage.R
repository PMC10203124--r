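# Devitrification and damage predictions.
#
# Damage begins wherever the steady-state temperature exceeds Tmax (~136 K):
# first at the square centre, then spreading outward as the power rises.
# Observed post-illumination squares fall into four ordinal states, from
# unaffected (1) through onset at the centre (2) and pronounced central
# damage (3) to destruction across the square (4).

#' Maximum safe illumination power density (closed form)
#'
#' For uniform illumination of a holey film, the absorbed power density is
#' `eta_c * P` (holes absorb nothing), so the peak temperature reaches the
#' devitrification threshold at
#' `P_max = 8 (Tmax - T0) / (alpha * eta_c * L^2)`.
#' This is the conservation law behind film-geometry selection: at fixed
#' material and mesh, `eta_c * P_max` is constant, so films with larger
#' holes and smaller spacings sustain proportionally more light.
#'
#' @param alpha_eff Effective film parameter, K um^-2 (W/cm^2)^-1.
#' @param L Grid-square size, um.
#' @param T0 Sink temperature, K.
#' @param Tmax Devitrification threshold, K.
#' @param eta_c Material area fraction of the film (1 = continuous).
#' @return Maximum power density in W/cm^2.
#' @export
max_power_density <- function(alpha_eff, L, T0 = 77, Tmax = 136, eta_c = 1) {
  stopifnot(alpha_eff > 0, L > 0, Tmax > T0, eta_c > 0, eta_c <= 1)
  8 * (Tmax - T0) / (alpha_eff * eta_c * L^2)
}

#' Maximum safe power density from the 2D solver
#'
#' Numerical counterpart of [max_power_density()] for arbitrary beams and
#' explicit hole masks: finds the peak illumination power density at which
#' the hottest pixel of the steady 2D field reaches `Tmax`, by bisection to
#' a relative tolerance. The spatial shape of the source (beam profile
#' times film mask) is solved once and rescaled, which the linearity of the
#' heat equation makes exact.
#'
#' @param spec A [grid_spec()].
#' @param params A [thermal_params()] with calibrated `alpha_eff`
#'   (per-material, before the area-fraction scaling: the hole mask supplies
#'   the geometry explicitly).
#' @param beam A [beam_profile()]; its `P` sets the initial bracket scale
#'   only. Default: uniform unit beam.
#' @param resolution Pixels per um for the solve.
#' @param tol Relative bisection tolerance.
#' @return Maximum peak power density in W/cm^2.
#' @export
max_power_density_2d <- function(spec, params,
                                 beam = beam_profile("uniform", P = 1),
                                 resolution = 1, tol = 1e-6) {
  stopifnot(inherits(spec, "grid_spec"), inherits(params, "thermal_params"))
  L <- spec$square_size
  unit_beam <- beam
  unit_beam$P <- 1
  shape <- intensity_map(unit_beam, L, resolution) *
    film_mask(spec, resolution)
  field1 <- steady_2d(shape, params$alpha_eff, L, L, T0 = params$T0,
                      resolution = resolution)
  rise1 <- max(field1$values) - params$T0   # peak rise per unit peak power
  if (rise1 <= 0) stop("source absorbs nowhere; P_max is unbounded")
  peak_at <- function(P) params$T0 + P * rise1
  target <- params$Tmax
  lo <- 0
  hi <- max(beam$P, 1)
  while (peak_at(hi) < target) hi <- hi * 2
  while ((hi - lo) > tol * hi) {
    mid <- (lo + hi) / 2
    if (peak_at(mid) < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Half-width of the damaged region
#'
#' Width of the central region where the parabolic 1D profile exceeds the
#' damage threshold. Zero at or below the threshold power; above it,
#' `(L/2) sqrt(1 - P_threshold / P)`, approaching `L/2` (the whole square)
#' as the power grows.
#'
#' @param P Applied power density, W/cm^2 (> 0).
#' @param P_threshold Threshold power density for the grid, W/cm^2.
#' @param L Grid-square size, um.
#' @return Damage half-width in um (vectorised over `P`).
#' @export
damage_half_width <- function(P, P_threshold, L) {
  stopifnot(all(P > 0), P_threshold > 0, L > 0)
  unname((L / 2) * sqrt(pmax(0, 1 - P_threshold / P)))
}

#' Classify a temperature field into a damage state
#'
#' Maps a steady-state field to the four-state ordinal damage scale by the
#' fraction of the square hotter than `Tmax`: state 1 when nothing exceeds
#' the threshold, state 2 (onset confined to the centre) up to `f_onset`,
#' state 3 up to `f_severe`, state 4 beyond. The state boundaries are area
#' fractions chosen to mirror the visual scale ("barely discernible at the
#' centre" vs "a large fraction of the area") and are configurable.
#'
#' @param field A `temperature_field` (1D or 2D).
#' @param Tmax Devitrification threshold, K.
#' @param f_onset Area fraction separating states 2 and 3 (default 0.05).
#' @param f_severe Area fraction separating states 3 and 4 (default 0.50).
#' @return A `damage_assessment`: list with `state` (1-4),
#'   `fraction_above_Tmax`, `affected_half_width` (um; equivalent radius in
#'   2D) and `peak_T` (K).
#' @export
classify_state <- function(field, Tmax = 136, f_onset = 0.05,
                           f_severe = 0.50) {
  stopifnot(inherits(field, "temperature_field"),
            0 < f_onset, f_onset < f_severe, f_severe < 1)
  above <- field$values > Tmax
  frac <- mean(above)
  if (field$dimensionality == 1L) {
    half_width <- if (any(above)) diff(range(field$x[above])) / 2 else 0
  } else {
    # equivalent radius of the affected area
    h2 <- (field$x[2] - field$x[1])^2
    half_width <- sqrt(sum(above) * h2 / pi)
  }
  state <- if (frac == 0) 1L else if (frac <= f_onset) 2L
           else if (frac <= f_severe) 3L else 4L
  out <- list(state = state, fraction_above_Tmax = frac,
              affected_half_width = half_width, peak_T = max(field$values))
  class(out) <- "damage_assessment"
  out
}

#' @export
print.damage_assessment <- function(x, ...) {
  cat(sprintf("<damage_assessment> state %d, %.1f%% of area above threshold, peak %.2f K\n",
              x$state, 100 * x$fraction_above_Tmax, x$peak_T))
  invisible(x)
}

#' Recommended operating power for imaging
#'
#' Operating at 70% of the measured or predicted damage threshold leaves
#' margin for the factors the model does not capture (ice thickness, film
#' integrity, sample composition), which shift the absolute threshold from
#' grid to grid.
#'
#' @param predicted_Pmax Predicted or measured maximum power density,
#'   W/cm^2 (> 0).
#' @param grid_id Optional identifier carried into the result.
#' @param safety_factor Fraction of the threshold to operate at
#'   (default 0.70).
#' @return List with `grid_id`, `predicted_Pmax` and `recommended_P`.
#' @export
recommend_operating_power <- function(predicted_Pmax, grid_id = NA_character_,
                                      safety_factor = 0.70) {
  if (!is.numeric(predicted_Pmax) || predicted_Pmax <= 0)
    stop("invalid parameter: `predicted_Pmax` must be positive")
  stopifnot(safety_factor > 0, safety_factor < 1)
  list(grid_id = grid_id, predicted_Pmax = predicted_Pmax,
       recommended_P = safety_factor * predicted_Pmax)
}

#' Damage-front progression under a power schedule
#'
#' Devitrification is irreversible: once a region has crystallised it stays
#' damaged even if the power is lowered. Under a stepwise power schedule
#' the damage half-width is therefore the running maximum of the
#' steady-state half-width over all powers seen so far — it grows when the
#' power is raised past previous levels and halts otherwise. A schedule
#' that never exceeds the threshold does no damage however long it runs:
#' damage is set by dose rate, not accumulated dose.
#'
#' @param schedule Data frame with columns `t` (strictly increasing times)
#'   and `P` (power densities, W/cm^2).
#' @param P_threshold Threshold power density, W/cm^2.
#' @param L Grid-square size, um.
#' @return The schedule with an appended `half_width` column (um).
#' @export
damage_front_progression <- function(schedule, P_threshold, L) {
  stopifnot(is.data.frame(schedule), all(c("t", "P") %in% names(schedule)))
  if (nrow(schedule) == 0) {
    schedule$half_width <- numeric(0)
    return(schedule)
  }
  if (any(diff(schedule$t) <= 0))
    stop("schedule times must be strictly increasing")
  w <- damage_half_width(schedule$P, P_threshold, L)
  schedule$half_width <- cummax(w)
  schedule
}
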