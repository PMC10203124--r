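# Steady-state and transient heat transport over one grid square.
#
# Model: the film absorbs incident light and heats; the metal bars bound the
# square and are ideal heat sinks pinned at the stage temperature T0 (77 K
# under liquid nitrogen). Convective cooling by the cold gas is negligible
# against conduction and is not modelled. All material constants (film
# absorptivity over thermal conductance, thickness) are lumped into a single
# effective parameter alpha with units K um^-2 (W/cm^2)^-1, so the source
# term is alpha * q with q the locally absorbed power density.
#
# 1D: d^2 T / dx^2 = -alpha P,  T(0) = T(L) = T0
#     => T(x) = T0 + (alpha P / 2) x (L - x), peak T0 + alpha P L^2 / 8.
# 2D: laplacian(T) = -alpha q(x, y), T = T0 on all four edges.

#' Thermal parameters of the model
#'
#' @param T0 Heat-sink (stage) temperature in K. Default 77 K, liquid
#'   nitrogen.
#' @param Tmax Damage-onset temperature in K. Default 136 K, where amorphous
#'   ice devitrifies into cubic ice.
#' @param alpha_eff Effective film parameter alpha in
#'   K um^-2 (W/cm^2)^-1: the lumped ratio of film absorptivity to thermal
#'   conductance. Calibrated from threshold measurements via [fit_alpha()],
#'   never taken from handbook values.
#' @return An object of class `thermal_params`.
#' @export
thermal_params <- function(T0 = 77, Tmax = 136, alpha_eff = NA_real_) {
  stopifnot(T0 > 0, Tmax > T0)
  if (!is.na(alpha_eff)) stopifnot(alpha_eff > 0)
  out <- list(T0 = T0, Tmax = Tmax, alpha_eff = alpha_eff)
  class(out) <- "thermal_params"
  out
}

# Internal constructor for temperature fields.
new_temperature_field <- function(values, T0, x, y = NULL) {
  out <- list(dimensionality = if (is.null(y)) 1L else 2L,
              x = x, y = y, values = values, T0 = T0)
  class(out) <- "temperature_field"
  out
}

#' @export
print.temperature_field <- function(x, ...) {
  if (x$dimensionality == 1L) {
    cat(sprintf("<temperature_field> 1D, %d points on [0, %.3g] um, T0 = %g K, peak = %.4f K\n",
                length(x$values), max(x$x), x$T0, max(x$values)))
  } else {
    cat(sprintf("<temperature_field> 2D, %d x %d pixels, T0 = %g K, peak = %.4f K\n",
                nrow(x$values), ncol(x$values), x$T0, max(x$values)))
  }
  invisible(x)
}

#' Steady-state 1D temperature profile across a grid square
#'
#' Closed-form solution of the steady heat equation with a uniform source
#' and both ends pinned at the sink temperature:
#' `T(x) = T0 + (alpha P / 2) x (L - x)`. The profile is parabolic, peaking
#' at the square centre, which is why light-induced damage always starts
#' there.
#'
#' @param P Absorbed illumination power density, W/cm^2 (>= 0).
#' @param alpha_eff Effective film parameter, K um^-2 (W/cm^2)^-1.
#' @param L Grid-square size, um.
#' @param T0 Sink temperature, K.
#' @param n_points Number of sample points across `[0, L]`.
#' @return A `temperature_field` (1D).
#' @export
steady_1d <- function(P, alpha_eff, L, T0 = 77, n_points = 201) {
  if (!is.numeric(P) || length(P) != 1 || P < 0)
    stop("invalid parameter: P must be a single non-negative power density")
  stopifnot(alpha_eff > 0, L > 0, n_points >= 2)
  x <- seq(0, L, length.out = n_points)
  Tv <- T0 + (alpha_eff * P / 2) * x * (L - x)
  new_temperature_field(Tv, T0, x)
}

#' Peak steady-state temperature for uniform illumination
#'
#' The 1D profile peaks at the square centre with
#' `T_peak = T0 + alpha P L^2 / 8`: linear in the power density and
#' quadratic in the square size, which is why halving the bar spacing
#' quadruples the sustainable power.
#'
#' @inheritParams steady_1d
#' @return Peak temperature in K.
#' @export
peak_temperature <- function(P, alpha_eff, L, T0 = 77) {
  if (!is.numeric(P) || any(P < 0))
    stop("invalid parameter: P must be non-negative")
  T0 + alpha_eff * P * L^2 / 8
}

# Assemble the cell-centred 5-point Laplacian system for an nx x ny pixel
# raster with Dirichlet value T0 on all four edges (boundary lies half a
# pixel beyond the outermost pixel centres; ghost values are eliminated by
# linear reflection, keeping the scheme second order). Returns the SPD
# matrix A (= -laplacian) and the boundary contribution to the right-hand
# side, both scaled by 1/h^2.
assemble_poisson <- function(nx, ny, h, T0) {
  n <- nx * ny
  i_row <- rep(seq_len(ny), times = nx)
  j_col <- rep(seq_len(nx), each = ny)
  id <- function(i, j) (j - 1L) * ny + i
  ii <- integer(0); jj <- integer(0)
  diagv <- rep(4, n)
  for (shift in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
    i2 <- i_row + shift[1]; j2 <- j_col + shift[2]
    inside <- i2 >= 1L & i2 <= ny & j2 >= 1L & j2 <= nx
    ii <- c(ii, id(i_row, j_col)[inside])
    jj <- c(jj, id(i2, j2)[inside])
    diagv[id(i_row, j_col)[!inside]] <- diagv[id(i_row, j_col)[!inside]] + 1
  }
  A <- Matrix::sparseMatrix(i = c(ii, seq_len(n)), j = c(jj, seq_len(n)),
                            x = c(rep(-1, length(ii)), diagv),
                            dims = c(n, n)) / h^2
  n_missing <- diagv - 4
  b_boundary <- 2 * T0 * n_missing / h^2
  list(A = A, b_boundary = b_boundary)
}

#' Steady-state 2D temperature field over a grid square
#'
#' Solves `laplacian(T) = -alpha q(x, y)` with all four edges pinned at the
#' sink temperature, by a 5-point finite-difference discretisation at pixel
#' centres and a direct sparse solve. The source raster is the locally
#' absorbed power density, typically `intensity_map(beam, ...) *
#' film_mask(spec, ...)` so that holes in the film absorb nothing.
#'
#' @param source Matrix of absorbed power density per pixel, W/cm^2
#'   (rows = y, columns = x; pixel convention of [film_mask()]).
#' @param alpha_eff Effective film parameter, K um^-2 (W/cm^2)^-1.
#' @param Lx,Ly Square (or rectangle) dimensions in um.
#' @param T0 Sink temperature, K.
#' @param resolution Pixels per um; must match `dim(source)` and give at
#'   least 32 pixels across the smaller dimension.
#' @return A `temperature_field` (2D) with the pixel-centre coordinates.
#' @export
steady_2d <- function(source, alpha_eff, Lx, Ly = Lx, T0 = 77,
                      resolution = ncol(source) / Lx) {
  stopifnot(is.matrix(source), all(source >= 0), alpha_eff > 0,
            Lx > 0, Ly > 0)
  ny <- nrow(source); nx <- ncol(source)
  if (abs(nx - Lx * resolution) > 0.5 || abs(ny - Ly * resolution) > 0.5)
    stop("solver error: source raster is ", ny, " x ", nx,
         " but Lx, Ly and resolution imply ",
         round(Ly * resolution), " x ", round(Lx * resolution))
  if (min(nx, ny) < 32)
    stop("solver error: need >= 32 pixels across the smaller dimension")
  h <- 1 / resolution
  sys <- assemble_poisson(nx, ny, h, T0)
  b <- alpha_eff * as.vector(source) + sys$b_boundary
  Tv <- as.numeric(Matrix::solve(sys$A, b))
  res <- as.numeric(sys$A %*% Tv - b)
  rel <- sqrt(sum(res^2)) / max(sqrt(sum(b^2)), .Machine$double.eps)
  if (rel > 1e-10)
    stop("solver error: relative residual ", format(rel), " exceeds 1e-10; ",
         "system size ", nx * ny)
  coords_x <- (seq_len(nx) - 0.5) * h
  coords_y <- (seq_len(ny) - 0.5) * h
  new_temperature_field(matrix(Tv, ny, nx), T0, coords_x, coords_y)
}

#' Transient 2D temperature evolution
#'
#' Integrates `tau dT/dt = laplacian(T) + alpha q` from an initial field to
#' `t_end`, with the same spatial discretisation and boundary conditions as
#' [steady_2d()]. `tau` sets the equilibration time constant; in the real
#' system the thermal mass is tiny and equilibration takes milliseconds,
#' which is why the steady-state model suffices and damage is governed by
#' dose rate, not dose. The implicit (backward-Euler) scheme is
#' unconditionally stable and is the default; the explicit scheme is
#' offered for cross-checking and enforces its stability bound
#' `dt <= tau h^2 / 4`.
#'
#' @inheritParams steady_2d
#' @param tau Heat-capacity time constant (time units per um^-2 of
#'   diffusion); the solution approaches steady state on the scale
#'   `tau (L / pi)^2`.
#' @param dt Time step.
#' @param t_end Final time.
#' @param T_init Initial field matrix; defaults to uniform `T0`.
#' @param scheme `"implicit"` (default) or `"explicit"`.
#' @param save_every Store every k-th step (the final field is always
#'   stored).
#' @return List with `times` and `fields` (list of `temperature_field`s).
#' @export
transient_2d <- function(source, alpha_eff, Lx, Ly = Lx, T0 = 77,
                         resolution = ncol(source) / Lx, tau = 1,
                         dt, t_end, T_init = NULL,
                         scheme = c("implicit", "explicit"),
                         save_every = 1L) {
  scheme <- match.arg(scheme)
  stopifnot(is.matrix(source), tau > 0, dt > 0, t_end >= dt)
  ny <- nrow(source); nx <- ncol(source)
  h <- 1 / resolution
  if (scheme == "explicit" && dt > tau * h^2 / 4)
    stop("unstable time step: explicit scheme requires dt <= tau h^2 / 4 = ",
         format(tau * h^2 / 4), " for this raster")
  sys <- assemble_poisson(nx, ny, h, T0)
  b <- alpha_eff * as.vector(source) + sys$b_boundary
  Tv <- if (is.null(T_init)) rep(T0, nx * ny) else as.vector(T_init)
  stopifnot(length(Tv) == nx * ny)
  n_steps <- ceiling(t_end / dt)
  coords_x <- (seq_len(nx) - 0.5) * h
  coords_y <- (seq_len(ny) - 0.5) * h
  times <- numeric(0); fields <- list()
  if (scheme == "implicit") {
    M <- sys$A + Matrix::Diagonal(nx * ny, tau / dt)
    fac <- Matrix::Cholesky(Matrix::forceSymmetric(M))
  }
  for (k in seq_len(n_steps)) {
    if (scheme == "implicit") {
      rhs <- (tau / dt) * Tv + b
      Tv <- as.numeric(Matrix::solve(fac, rhs))
    } else {
      Tv <- Tv + (dt / tau) * (b - as.numeric(sys$A %*% Tv))
    }
    if (k %% save_every == 0L || k == n_steps) {
      times <- c(times, k * dt)
      fields[[length(fields) + 1L]] <-
        new_temperature_field(matrix(Tv, ny, nx), T0, coords_x, coords_y)
    }
  }
  list(times = times, fields = fields)
}

#' Export a temperature field as a CSV matrix with a JSON sidecar
#'
#' Writes the field values as a plain CSV matrix (no header) plus a
#' `<path>.json` metadata sidecar recording the geometry, sink temperature
#' and resolution. Set `tiff = TRUE` to additionally write a 32-bit float
#' TIFF raster next to the CSV (requires the `tiff` package).
#'
#' @param field A `temperature_field`.
#' @param path Output CSV path.
#' @param tiff Also write `<path>.tif`?
#' @return Invisibly, the CSV path.
#' @export
write_field <- function(field, path, tiff = FALSE) {
  stopifnot(inherits(field, "temperature_field"))
  vals <- if (field$dimensionality == 1L) matrix(field$values, nrow = 1)
          else field$values
  utils::write.table(vals, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(dimensionality = field$dimensionality,
               T0_K = field$T0,
               peak_K = max(field$values),
               Lx_um = max(field$x) + if (field$dimensionality == 2L)
                 field$x[1] else 0,
               n_x = length(field$x),
               n_y = if (is.null(field$y)) 1L else length(field$y))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  if (tiff) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the `tiff` package is required for TIFF export")
    tiff::writeTIFF(vals / max(vals), paste0(path, ".tif"),
                    bits.per.sample = 32L)
  }
  invisible(path)
}
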