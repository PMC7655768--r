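test_that("stlsq recovers an exactly constructed sparse target", {
  A <- withr::with_seed(4, matrix(rnorm(300), 50, 6))
  colnames(A) <- paste0("c", 1:6)
  b <- 2 * A[, 3]
  fit <- stlsq(A, b, 0.5)
  expect_equal(unname(which(fit$support)), 3)
  expect_equal(unname(fit$coef[3]), 2, tolerance = 1e-8)
  expect_lt(fit$relative_residual, 1e-8)
})

test_that("stlsq flags the empty model when lambda dominates", {
  A <- withr::with_seed(5, matrix(rnorm(200), 50, 4))
  b <- withr::with_seed(6, rnorm(50))
  fit <- stlsq(A, b, 50)
  expect_true(fit$empty_model)
  expect_true(all(fit$coef == 0))
  expect_true(fit$converged)
})

test_that("stlsq is a fixed point at convergence", {
  A <- withr::with_seed(7, matrix(rnorm(300), 50, 6))
  b <- A %*% c(3, 0, -2, 0, 0, 1) + withr::with_seed(8, rnorm(50, 0, 0.01))
  f1 <- stlsq(A, b, 0.1, max_iter = 25)
  f2 <- stlsq(A, b, 0.1, max_iter = 26)
  expect_identical(f1$support, f2$support)
  expect_equal(f1$coef, f2$coef)
  expect_true(f1$converged)
})

test_that("support size is non-increasing in lambda", {
  A <- withr::with_seed(9, matrix(rnorm(400), 50, 8))
  b <- A %*% c(5, -3, 1, 0.5, 0, 0, 0, 0) + withr::with_seed(10, rnorm(50, 0, 0.05))
  sizes <- vapply(c(0.05, 0.1, 0.2, 0.5, 1, 2), function(l)
    sum(stlsq(A, b, l)$support), 0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("stlsq agrees with exhaustive best-subset search on small problems", {
  hits <- 0
  for (s in 1:200) {
    dat <- withr::with_seed(1000 + s, {
      A <- matrix(rnorm(180), 30, 6)
      supp <- sample(6, 2)
      coefs <- sample(c(-1, 1), 2, replace = TRUE) * runif(2, 2, 4)
      b <- A[, supp] %*% coefs + rnorm(30, 0, 0.05)
      list(A = A, b = as.numeric(b), supp = sort(supp))
    })
    fit <- stlsq(dat$A, dat$b, 0.3)
    oracle <- best_subset_support(dat$A, dat$b, kmax = 2)
    hits <- hits + identical(unname(which(fit$support)), oracle)
  }
  expect_gte(hits / 200, 0.95)
})

test_that("the constrained joint solve zeroes the diagonal and matches per-column fits", {
  data <- mm_quick_data()
  lib <- build_library(data, mm_library_spec())
  Xi <- constrained_joint_solve(lib, lambda = 0.2)
  expect_true(all(diag(Xi) == 0))
  j <- match("x*dx", lib$labels)
  sp <- split_candidate(lib, j)
  ref <- stlsq(sp$reduced$values, sp$lhs, 0.2)
  expect_equal(unname(Xi[-j, j]), unname(ref$coef), tolerance = 1e-8)
})

test_that("the constrained solve recovers a planted exact linear relation", {
  vals <- withr::with_seed(12, matrix(rnorm(400), 100, 4))
  vals <- cbind(vals, 2 * vals[, 1] - 3 * vals[, 2])   # col5 = 2c1 - 3c2
  colnames(vals) <- paste0("c", 1:5)
  terms <- lapply(colnames(vals), new_term_for_test)
  lib <- structure(list(values = vals, terms = terms,
                        labels = colnames(vals), norms = NULL,
                        zero = rep(FALSE, 5), spec = NULL),
                   class = "library_matrix")
  Xi <- constrained_joint_solve(lib, lambda = 0.1)
  expect_equal(unname(Xi[c(1, 2), 5]), c(2, -3), tolerance = 1e-8)
  expect_equal(unname(Xi[c(3, 4), 5]), c(0, 0))
})

test_that("ADM finds the implicit relation of noiseless enzyme kinetics", {
  data <- mm_quick_data()
  lib <- build_library(data, mm_library_spec())
  fit <- adm_implicit_sindy(lib, cutoff = 1e-6, prune = 1e-3, seed = 1)
  expect_equal(sum(fit$coef^2), 1, tolerance = 1e-12)   # unit norm
  first <- fit$coef[fit$coef != 0][1]
  expect_gt(first, 0)                                   # sign convention
  supp <- sort(names(fit$coef)[fit$support])
  families <- lapply(mm_truth_family(), sort)
  expect_true(any(vapply(families, identical, TRUE, supp)))
})

test_that("a full-rank noisy library has no numerical null space at a tight cutoff", {
  vals <- withr::with_seed(13, matrix(rnorm(600), 100, 6))
  colnames(vals) <- paste0("c", 1:6)
  terms <- lapply(colnames(vals), new_term_for_test)
  lib <- structure(list(values = vals, terms = terms,
                        labels = colnames(vals), norms = NULL,
                        zero = rep(FALSE, 6), spec = NULL),
                   class = "library_matrix")
  expect_equal(nullspace_dimension(lib, 1e-8), 0)
  expect_error(adm_implicit_sindy(lib, cutoff = 1e-8), "no null space")
})

test_that("noise closes the numerical null space of the implicit library", {
  # the mechanism behind the baseline's noise fragility: the relation
  # singular values rise with measurement noise until no direction
  # falls below the cutoff
  clean <- mm_quick_data()
  dims <- vapply(c(0, 1e-6, 1e-4, 1e-2), function(sig) {
    noisy <- add_noise(clean, sig, seed = 77)
    vars <- cbind(x = noisy$X[, "x"], dx = clean$Xdot[, "dx"])
    nullspace_dimension(build_library(vars, mm_library_spec()), 1e-5)
  }, 0)
  expect_equal(dims[1], 2)           # the relation and its x-multiple
  expect_true(all(diff(dims) <= 0))  # monotone collapse with noise
  expect_equal(dims[4], 0)
})
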