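# Steady and transient heat solvers against independent oracles.

# Finite-difference oracle for the 1D problem: solve the tridiagonal system
# for d2T/dx2 = -alpha P with T(0) = T(L) = T0 directly.
fd_steady_1d <- function(P, alpha, L, T0, n_interior = 199) {
  h <- L / (n_interior + 1)
  A <- diag(-2, n_interior)
  A[cbind(1:(n_interior - 1), 2:n_interior)] <- 1
  A[cbind(2:n_interior, 1:(n_interior - 1))] <- 1
  b <- rep(-alpha * P * h^2, n_interior)
  b[1] <- b[1] - T0
  b[n_interior] <- b[n_interior] - T0
  c(T0, solve(A, b), T0)
}

# Series oracle for -laplacian(u) = 1 on the unit square, u = 0 on the
# boundary: 1D parabola minus the boundary-layer correction. The sinh ratio
# is evaluated in exponential form to avoid overflow at large k.
poisson_unit_square <- function(x, y, kmax = 199) {
  s <- x * (1 - x) / 2
  for (k in seq(1, kmax, by = 2)) {
    a <- k * pi
    ratio <- (exp(a * (y - 1)) - exp(-a * (y + 1)) +
                exp(-a * y) - exp(-a * (2 - y))) / (1 - exp(-2 * a))
    s <- s - 4 / (pi^3 * k^3) * sin(a * x) * ratio
  }
  s
}

test_that("1D closed form matches the finite-difference oracle", {
  P <- 64; alpha <- 2.19e-3; L <- 58; T0 <- 77
  oracle <- fd_steady_1d(P, alpha, L, T0)
  x <- seq(0, L, length.out = length(oracle))
  field <- steady_1d(P, alpha, L, T0, n_points = length(oracle))
  rise <- max(field$values) - T0
  expect_lt(max(abs(field$values - oracle)), 1e-9 * rise)
  # boundary and shape
  expect_equal(field$values[1], T0)
  expect_equal(field$values[length(oracle)], T0)
  expect_equal(max(field$values), T0 + P * alpha * L^2 / 8, tolerance = 1e-12)
})

test_that("1D profile degenerates correctly and rejects bad input", {
  f0 <- steady_1d(0, 1e-3, 58, T0 = 77)
  expect_true(all(f0$values == 77))
  expect_error(steady_1d(-5, 1e-3, 58), "invalid parameter")
})

test_that("peak temperature scales linearly in P and quadratically in L", {
  rise <- function(P, L) peak_temperature(P, 2e-3, L) - 77
  expect_equal(rise(100, 58), 2 * rise(50, 58), tolerance = 1e-12)
  expect_equal(rise(50, 116), 4 * rise(50, 58), tolerance = 1e-12)
  # calibration at the 300-mesh threshold: alpha such that the peak reaches
  # the devitrification temperature at 64 W/cm^2 over a 58 um square
  alpha <- 8 * (136 - 77) / (64 * 58^2)
  expect_equal(alpha, 2.193e-3, tolerance = 1e-3)
  expect_equal(peak_temperature(64, alpha, 58), 136, tolerance = 1e-12)
})

test_that("2D solver reproduces the unit-square Poisson benchmark", {
  n <- 65
  field <- steady_2d(matrix(1, n, n), alpha_eff = 1, Lx = 1, Ly = 1,
                     T0 = 0, resolution = n)
  peak_oracle <- poisson_unit_square(0.5, 0.5)
  expect_equal(peak_oracle, 0.0736713, tolerance = 1e-6)
  expect_equal(max(field$values), peak_oracle, tolerance = 1e-4 / peak_oracle)
  # interior-point check away from the centre, at the pixel coordinate
  ix <- which.min(abs(field$x - 0.25))
  expect_equal(field$values[ix, ix],
               poisson_unit_square(field$x[ix], field$x[ix]),
               tolerance = 2e-3)
})

test_that("2D peak error shrinks as O(h^2) under refinement", {
  peak_oracle <- poisson_unit_square(0.5, 0.5)
  errs <- vapply(c(33, 65), function(n) {
    f <- steady_2d(matrix(1, n, n), 1, 1, 1, T0 = 0, resolution = n)
    abs(max(f$values) - peak_oracle)
  }, numeric(1))
  expect_gt(errs[1] / errs[2], 3)  # halving h should shrink error ~4x
})

test_that("2D solutions obey symmetry, the maximum principle and superposition", {
  n <- 48
  set.seed(7)
  half <- matrix(runif(n * n / 2), n, n / 2)
  q_sym <- cbind(half, half[, (n / 2):1])  # symmetric under x reflection
  f <- steady_2d(q_sym, 1e-3, 2, 2, T0 = 77, resolution = n / 2)
  expect_lt(max(abs(f$values - f$values[, n:1])), 1e-10)
  expect_gte(min(f$values), 77)
  # boundary-adjacent pixels approach the sink temperature
  expect_lt(max(f$values[1, ]) - 77, 0.1 * (max(f$values) - 77))
  # superposition of sources adds temperature rises
  q1 <- matrix(runif(n * n), n, n)
  q2 <- matrix(runif(n * n), n, n)
  f1 <- steady_2d(q1, 1e-3, 2, 2, T0 = 77, resolution = n / 2)
  f2 <- steady_2d(q2, 1e-3, 2, 2, T0 = 77, resolution = n / 2)
  f12 <- steady_2d(q1 + q2, 1e-3, 2, 2, T0 = 77, resolution = n / 2)
  expect_lt(max(abs(f12$values - (f1$values + f2$values - 77))), 1e-8)
})

test_that("an elongated 2D solve recovers the 1D profile on its central row", {
  Lx <- 1; Ly <- 8; res <- 32
  q <- matrix(1, Ly * res, Lx * res)
  f2 <- steady_2d(q, alpha_eff = 5, Lx = Lx, Ly = Ly, T0 = 10,
                  resolution = res)
  mid <- round(nrow(q) / 2)
  f1 <- steady_1d(1, 5, Lx, T0 = 10, n_points = 1001)
  rise <- max(f1$values) - 10
  interp <- stats::approx(f1$x, f1$values, xout = f2$x)$y
  expect_lt(max(abs(f2$values[mid, ] - interp)), 0.01 * rise)
})

test_that("2D solver rejects inconsistent rasters", {
  expect_error(steady_2d(matrix(1, 40, 40), 1, Lx = 1, Ly = 1,
                         resolution = 64), "solver error")
  expect_error(steady_2d(matrix(1, 16, 16), 1, Lx = 1, Ly = 1,
                         resolution = 16), "32")
})

test_that("transient solver relaxes to the steady state", {
  n <- 32
  q <- matrix(1, n, n)
  steady <- steady_2d(q, 1, 1, 1, T0 = 0, resolution = n)
  rise <- max(steady$values)
  tr <- transient_2d(q, 1, 1, 1, T0 = 0, resolution = n, tau = 1,
                     dt = 0.01, t_end = 2, save_every = 20)
  final <- tr$fields[[length(tr$fields)]]$values
  expect_lt(max(abs(final - steady$values)), 1e-6 * rise)
  # from a cold start with constant source, convergence is pointwise monotone
  for (k in seq_len(length(tr$fields) - 1)) {
    expect_true(all(tr$fields[[k + 1]]$values - tr$fields[[k]]$values >= -1e-12))
  }
  # time-step refinement barely changes the converged field
  tr2 <- transient_2d(q, 1, 1, 1, T0 = 0, resolution = n, tau = 1,
                      dt = 0.005, t_end = 2, save_every = 1e6)
  expect_lt(max(abs(tr2$fields[[1]]$values - final)), 1e-6)
})

test_that("transient schemes agree and the explicit stability bound is enforced", {
  n <- 32
  q <- matrix(1, n, n)
  h <- 1 / n
  expect_error(transient_2d(q, 1, 1, 1, T0 = 0, resolution = n, tau = 1,
                            dt = h^2, t_end = 1, scheme = "explicit"),
               "unstable")
  dt_ok <- 0.9 * h^2 / 4
  ex <- transient_2d(q, 1, 1, 1, T0 = 0, resolution = n, tau = 1,
                     dt = dt_ok, t_end = 0.5, scheme = "explicit",
                     save_every = 1e6)
  im <- transient_2d(q, 1, 1, 1, T0 = 0, resolution = n, tau = 1,
                     dt = dt_ok, t_end = 0.5, scheme = "implicit",
                     save_every = 1e6)
  expect_lt(max(abs(ex$fields[[1]]$values - im$fields[[1]]$values)), 1e-4)
  # zero source: the field stays at the sink temperature
  tz <- transient_2d(matrix(0, n, n), 1, 1, 1, T0 = 5, resolution = n,
                     tau = 1, dt = 0.05, t_end = 0.5, save_every = 1e6)
  expect_true(all(abs(tz$fields[[1]]$values - 5) < 1e-12))
})

test_that("fields export as CSV with a JSON sidecar", {
  f <- steady_1d(64, 2.19e-3, 58, n_points = 11)
  path <- tempfile(fileext = ".csv")
  write_field(f, path)
  vals <- as.numeric(read.csv(path, header = FALSE)[1, ])
  expect_equal(vals, as.numeric(f$values), tolerance = 1e-8)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$peak_K, max(f$values), tolerance = 1e-8)
  unlink(c(path, paste0(path, ".json")))
})
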