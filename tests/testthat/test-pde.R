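test_that("spectral spatial derivatives satisfy Fourier identities", {
  n <- 128
  x <- 2 * pi * (0:(n - 1)) / n
  fld <- field_data(x, c(0, 1), cbind(sin(x), sin(x)))
  d1 <- spatial_derivatives(fld, 1)
  expect_equal(d1[, 1], cos(x), tolerance = 1e-10, ignore_attr = TRUE)
  d3 <- spatial_derivatives(fld, 3)
  expect_equal(d3[, 1], -cos(x), tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(spatial_derivatives(matrix(1, n), dx = x[2], order = 1),
               matrix(0, n), tolerance = 1e-12)
  expect_error(spatial_derivatives(fld, 5), "maximum")
})

test_that("spectral and fourth-order finite differences agree on smooth fields", {
  n <- 128; L <- 40
  x <- -L / 2 + L * (0:(n - 1)) / n
  u <- sin(2 * pi * x / L) + 0.5 * cos(4 * pi * x / L)
  ds <- spatial_derivatives(u, dx = L / n, order = 1, scheme = "spectral")
  df <- spatial_derivatives(u, dx = L / n, order = 1, scheme = "fd")
  expect_lt(max(abs(ds - df)) / max(abs(ds)), 1e-5)
})

test_that("the modified KdV simulator preserves the pure-KdV mass invariant", {
  f0 <- simulate_modified_kdv(kdv_params(gamma = 0, g0 = 0), T = 5)
  mass <- colSums(f0$u) * f0$dx
  expect_lt(max(abs(mass - mass[1])) / abs(mass[1]), 1e-6)
})

test_that("the zero state is a fixed point of the lossy ungained equation", {
  f <- simulate_modified_kdv(kdv_params(gamma = 0.1, g0 = 0),
                             u0 = function(x) rep(0, length(x)), T = 1)
  expect_lt(max(abs(f$u)), 1e-12)
})

test_that("stored time derivatives are consistent with the evolution", {
  f <- simulate_modified_kdv(kdv_params(), T = 1, dt_out = 2e-3)
  n <- ncol(f$u)
  fd <- (f$u[, 3:n] - f$u[, 1:(n - 2)]) / (2 * f$dt)
  rel <- max(abs(f$ut[, 2:(n - 1)] - fd)) / max(abs(f$ut))
  expect_lt(rel, 0.02)
})

test_that("PDE library construction counts, values and trimming are right", {
  f <- simulate_modified_kdv(kdv_params(), T = 0.5)
  vars <- kdv_variables(f)
  spec <- kdv_library_spec()
  expect_length(enumerate_terms(spec), 24)
  lib <- build_pde_library(vars, spec, subsample = 500, seed = 1)
  expect_length(lib$labels, 24)
  # u * u_t column value by hand
  small <- list(u = matrix(2), u_x = matrix(0), u_xx = matrix(0),
                u_xxx = matrix(0), u_t = matrix(0.3))
  lib1 <- build_pde_library(small, spec)
  expect_equal(unname(lib1$values[1, match("u*u_t", lib1$labels)]), 0.6)
  # trim rule: drops `trim_time` slices at each end
  nt <- ncol(vars$u)
  libt <- build_pde_library(vars, spec, trim_time = 3)
  expect_equal(unname(attr(libt, "rows")["available"]),
               nrow(vars$u) * (nt - 6))
})

test_that("implicit PDE fitting recovers the rational structure at g0 = 1", {
  f <- simulate_modified_kdv(kdv_params(gamma = 0.1, g0 = 1), T = 5)
  fit <- fit_pde_implicit(kdv_variables(f), kdv_library_spec(),
                          candidates = c("u_t", "u*u_t"))
  expect_equal(structure_error(fit$winner, kdv_truth_support(1))$total, 0)
  ode <- normalize_rational(fit$winner_ode, by = "constant")
  expect_equal(-rational_coef(ode, "u", "num"), 0.1, tolerance = 0.05)
  expect_equal(rational_coef(ode, "u*u_x", "num"), -6, tolerance = 0.05)
})

test_that("without gain the recovered PDE is explicit with unit denominator", {
  f <- simulate_modified_kdv(kdv_params(gamma = 0, g0 = 0), T = 5)
  fit <- fit_pde_implicit(kdv_variables(f), kdv_library_spec(),
                          candidates = c("u_t", "u*u_t"))
  ode <- normalize_rational(fit$winner_ode, by = "constant")
  expect_identical(ode$den$labels, "1")
  expect_equal(rational_coef(ode, "u*u_x", "num"), -6, tolerance = 1e-3)
  expect_equal(rational_coef(ode, "u_xxx", "num"), -1, tolerance = 1e-3)
  expect_error(fit_pde_implicit(kdv_variables(f), kdv_library_spec(),
                                candidates = character()), "empty candidate")
})

test_that("the explicit baseline works without gain and breaks with it", {
  f0 <- simulate_modified_kdv(kdv_params(gamma = 0.1, g0 = 0), T = 5)
  bl0 <- pdefind_baseline(kdv_variables(f0), kdv_library_spec(explicit = TRUE))
  expect_identical(bl0$support, sort(c("u", "u*u_x", "u_xxx")))
  expect_equal(unname(bl0$coef["u"]), -0.1, tolerance = 1e-3)
  expect_equal(unname(bl0$coef["u*u_x"]), -6, tolerance = 1e-3)
  expect_equal(unname(bl0$coef["u_xxx"]), -1, tolerance = 1e-3)

  f1 <- simulate_modified_kdv(kdv_params(gamma = 0.1, g0 = 1), T = 5)
  bl1 <- pdefind_baseline(kdv_variables(f1), kdv_library_spec(explicit = TRUE))
  truth_explicit <- sort(c("u", "u*u_x", "u_xxx"))
  expect_gt(structure_error(bl1$support, truth_explicit)$total, 0)

  # the implicit fit residual dwarfs the baseline's when gain is active
  fit1 <- fit_pde_implicit(kdv_variables(f1), kdv_library_spec(),
                           candidates = c("u_t", "u*u_t"))
  expect_gt(bl1$error / min(fit1$table$error, na.rm = TRUE), 1e3)
})

test_that("the baseline refuses a library containing its own target", {
  f <- simulate_modified_kdv(kdv_params(), T = 0.2)
  expect_error(pdefind_baseline(kdv_variables(f), kdv_library_spec()),
               "target")
})

test_that("the BZ solver matches an ODE oracle for uniform fields", {
  p0 <- bz_params(Dx = 0, Dz = 0, Ds = 0, Du = 0)
  u0 <- list(x = function(y) rep(0.4, length(y)),
             z = function(y) rep(0.3, length(y)),
             s = function(y) rep(0.2, length(y)),
             u = function(y) rep(0.25, length(y)))
  bz <- simulate_bz(p0, init = u0, n = 64, dt_out = 0.01)
  rhs <- function(t, y, p) list(unlist(sindypi:::bz_reaction(as.list(y), p)))
  sol <- deSolve::ode(c(x = 0.4, z = 0.3, s = 0.2, u = 0.25), bz$t, rhs, p0,
                      rtol = 1e-10, atol = 1e-12)
  for (nm in c("x", "z", "s", "u"))
    expect_lt(max(abs(bz$fields[[nm]][1, ] - sol[, nm])), 1e-8)
})

test_that("the BZ reaction terms match a hand-expanded evaluation", {
  p <- bz_params()
  st <- withr::with_seed(33, list(x = runif(20, 0.05, 0.8), z = runif(20, 0.1, 0.6),
                                  s = runif(20, 0.05, 0.4), u = runif(20, 0.05, 0.5)))
  r <- sindypi:::bz_reaction(st, p)
  x_by_hand <- (p$f * st$z * (p$q - st$x) / (p$q + st$x) +
                  st$x - st$x^2 - p$beta * st$x + st$s) / p$eps
  z_by_hand <- st$x - st$z - p$alpha * st$z + p$gamma * st$u
  expect_equal(r$x, x_by_hand, tolerance = 1e-12)
  expect_equal(r$z, z_by_hand, tolerance = 1e-12)
})

test_that("the spectral Laplacian reproduces the analytic form of a Gaussian", {
  n <- 128
  y <- -10 + 20 * (0:(n - 1)) / n
  g <- exp(-y^2 / (2 * 1.5^2))
  lap <- spatial_derivatives(g, dx = 20 / n, order = 2)
  analytic <- g * (y^2 / 1.5^4 - 1 / 1.5^2)
  expect_lt(max(abs(lap - analytic)), 1e-6)
})

test_that("the BZ activator equation is recovered from simulation data", {
  bz <- simulate_bz()
  expect_false(attr(bz, "aborted"))
  fit <- fit_pde_implicit(bz_x_variables(bz), bz_x_library_spec(),
                          candidates = c("x_t", "x*x_t"),
                          deriv_var = "x_t", subsample = 8000)
  expect_equal(structure_error(fit$winner, bz_x_truth_support())$total, 0)
})
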