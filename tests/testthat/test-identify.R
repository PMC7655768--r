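test_that("fitting the correct candidate recovers the cleared enzyme-kinetics relation", {
  data <- mm_quick_data()
  lib <- build_library(data, mm_unique_spec())
  m <- fit_candidate(lib, "x*dx", 0.1)
  # x*dx = jx*Km - (Vmax - jx)*x - Km*dx  with jx=0.6, Vmax=1.5, Km=0.3
  expect_equal(unname(m$coef["1"]), 0.18, tolerance = 1e-6)
  expect_equal(unname(m$coef["x"]), -0.9, tolerance = 1e-6)
  expect_equal(unname(m$coef["dx"]), -0.3, tolerance = 1e-6)
  expect_equal(unname(m$coef["x^2"]), 0)
  expect_lt(m$residual, 1e-6)
})

test_that("an identically zero candidate column is a degenerate lhs", {
  vars <- cbind(x = runif(30, 0.2, 1), y = 0, dx = rnorm(30))
  spec <- library_spec(states = c("x", "y"), derivs = c("dx", "dy"),
                       degree = 2, deriv_vars = "dx")
  lib <- build_library(vars, spec)
  expect_error(fit_candidate(lib, "y", 0.1), "degenerate lhs")
})

test_that("wrong candidates fit far worse than the correct one", {
  # a transient covering a wide concentration range, so no spurious
  # near-relation can mimic the constant candidate
  data <- simulate_michaelis_menten(x0 = 1.5, times = seq(0, 2.5, by = 0.01))
  lib <- build_library(data, mm_unique_spec())
  lambdas <- seq(0.1, 1, by = 0.1)
  res_good <- vapply(lambdas, function(l)
    fit_candidate(lib, "x*dx", l)$residual, 0)
  res_bad <- vapply(lambdas, function(l)
    fit_candidate(lib, "1", l)$residual, 0)
  expect_gt(min(res_bad), 10 * min(res_good))
})

test_that("sweeps are exhaustive, deterministic and respect the candidate restriction", {
  data <- mm_quick_data()
  lib <- build_library(data, mm_library_spec())
  lambdas <- c(0.1, 0.2, 0.5, 1)
  cands <- derivative_candidates(lib)
  expect_identical(cands, c("dx", "x*dx", "x^2*dx"))
  models <- sweep_candidates(lib, lambdas = lambdas)
  expect_length(models, length(cands) * length(lambdas))
  models2 <- sweep_candidates(lib, lambdas = lambdas)
  expect_identical(lapply(models, `[[`, "coef"),
                   lapply(models2, `[[`, "coef"))
  for (m in models)
    expect_true(any(names(m$lhs_term$powers) == "dx"))
})

test_that("per-fit failures are captured without aborting the sweep", {
  vars <- cbind(x = runif(30, 0.2, 1), y = 0, dx = rnorm(30))
  spec <- library_spec(states = c("x", "y"), derivs = c("dx", "dy"),
                       degree = 1, deriv_vars = "dx")
  lib <- build_library(vars, spec)
  models <- sweep_candidates(lib, candidates = c("y", "x"), lambdas = 0.1)
  expect_s3_class(models[[1]], "candidate_failure")
  expect_s3_class(models[[2]], "candidate_model")
})

test_that("implicit models rearrange exactly into rational form", {
  data <- mm_quick_data()
  lib <- build_library(data, mm_unique_spec())
  ode <- to_explicit_ode(fit_candidate(lib, "x*dx", 0.1))
  xs <- withr::with_seed(3, runif(100, 0.05, 2))
  pred <- vapply(xs, function(x) {
    nd <- sindypi:::eval_rational_point(ode, c(x = x))
    nd[["num"]] / nd[["den"]]
  }, 0)
  truth <- 0.6 - 1.5 * xs / (0.3 + xs)
  expect_equal(pred, truth, tolerance = 1e-6)
})

test_that("rational conversion rejects irreducible relations", {
  data <- mm_quick_data()
  lib <- build_library(data, mm_library_spec())
  m <- fit_candidate(lib, "1", 1e-3)   # no derivative on the lhs
  m$coef[] <- 0                         # and none on the rhs
  expect_error(to_explicit_ode(m, deriv_var = "dx"), "not reducible")
})

test_that("polynomial dynamics yield a constant denominator", {
  # xdot = 1 - x on a grid; implicit form dx + x - 1 = 0
  t <- seq(0, 5, by = 0.01)
  x <- 1 - 0.7 * exp(-t)
  vars <- cbind(x = x, dx = 0.7 * exp(-t))
  lib <- build_library(vars, mm_unique_spec(deriv_poly_cap = 0))
  ode <- to_explicit_ode(fit_candidate(lib, "dx", 0.1))
  oden <- normalize_rational(ode, by = "constant")
  expect_identical(oden$den$labels, "1")
  expect_equal(unname(oden$den$coef), 1)
})

test_that("identified models can be integrated and reproduce the dynamics", {
  data <- mm_quick_data()
  rep <- sindy_pi(data, mm_library_spec())
  times <- seq(0, 10, by = 0.01)
  sim <- simulate_identified(list(rep$winner_ode), c(x = 0.5), times)
  truth <- simulate_michaelis_menten(x0 = 0.5, times = times)
  expect_lt(max(abs(sim$X[, "x"] - truth$X[, "x"])), 1e-4)
  expect_false(attr(sim, "terminated_early"))
  # the fixed point jx*(Km+x) = Vmax*x sits at x = 0.2
  fp <- simulate_identified(list(rep$winner_ode), c(x = 0.2), times)
  expect_lt(max(abs(fp$X[, "x"] - 0.2)), 1e-3)
})

test_that("a vanishing denominator terminates the integration with a flag", {
  # dx/dt = 1 / (0.5 - x): denominator crosses zero at x = 0.5
  num <- list(terms = list(sindypi:::new_term(integer(0))),
              coef = 1, labels = "1")
  den <- list(terms = list(sindypi:::new_term(integer(0)),
                           new_term_for_test("x")),
              coef = c(0.5, -1), labels = c("1", "x"))
  ode <- structure(list(state = "x", deriv_var = "dx", num = num,
                        den = den, source_lhs = "dx", lambda = NA),
                   class = "rational_ode")
  sim <- simulate_identified(list(ode), c(x = 0), seq(0, 1, by = 0.01))
  expect_true(attr(sim, "terminated_early"))
  expect_lt(nrow(sim$X), 101)
})

test_that("structure error counts added and deleted terms", {
  s0 <- structure_error(c("a", "b", "c"), c("a", "b", "c"))
  expect_equal(c(s0$added, s0$deleted, s0$total), c(0, 0, 0))
  s1 <- structure_error(c("a", "b", "d"), c("a", "b", "c"))
  expect_equal(c(s1$added, s1$deleted, s1$total), c(1, 1, 2))
  s2 <- structure_error(character(), c("a", "b", "c"))
  expect_equal(c(s2$added, s2$deleted, s2$total), c(0, 3, 3))
})

test_that("structure error rejects mismatched vocabularies", {
  data <- mm_quick_data()
  lib <- build_library(data, mm_unique_spec())
  m <- fit_candidate(lib, "x*dx", 0.1)
  expect_error(structure_error(m, c("1", "x", "not_a_term")), "outside")
})

test_that("different correct candidates agree as rational functions", {
  data <- mm_quick_data()
  lib <- build_library(data, mm_unique_spec())
  ode1 <- to_explicit_ode(fit_candidate(lib, "dx", 0.9))
  ode2 <- to_explicit_ode(fit_candidate(lib, "x*dx", 0.1))
  xs <- withr::with_seed(5, runif(100, 0.05, 2))
  f <- function(ode) vapply(xs, function(x) {
    nd <- sindypi:::eval_rational_point(ode, c(x = x))
    nd[["num"]] / nd[["den"]]
  }, 0)
  expect_equal(f(ode1), f(ode2), tolerance = 1e-6)
})
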