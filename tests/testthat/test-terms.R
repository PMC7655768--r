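test_that("enumeration produces the expected monomial bases", {
  s1 <- library_spec(states = "x", deriv_vars = character(), degree = 2)
  t1 <- enumerate_terms(s1)
  expect_equal(vapply(t1, `[[`, "", "label"), c("1", "x", "x^2"))

  s2 <- library_spec(states = c("x", "y"), deriv_vars = character(), degree = 2)
  expect_length(enumerate_terms(s2), 6)  # C(2+2, 2) by stars and bars

  s3 <- library_spec(states = "phi", deriv_vars = character(), degree = 1,
                     poly_vars = character(), trig_vars = "phi")
  labs <- vapply(enumerate_terms(s3), `[[`, "", "label")
  expect_true(all(c("sin(phi)", "cos(phi)") %in% labs))
})

test_that("enumeration is duplicate-free, deterministic, constant-first", {
  spec <- library_spec(states = c("a", "b"), degree = 3,
                       trig_vars = "a", deriv_vars = "da")
  t1 <- enumerate_terms(spec)
  t2 <- enumerate_terms(spec)
  labs <- vapply(t1, `[[`, "", "label")
  expect_identical(labs, vapply(t2, `[[`, "", "label"))
  expect_false(anyDuplicated(labs) > 0)
  expect_identical(labs[1], "1")
  # squared sines are excluded so the trig block stays independent
  expect_false(any(grepl("sin\\(a\\)\\^", labs)))
})

test_that("invalid specifications are rejected", {
  expect_error(library_spec(states = "x", degree = -1), "degree")
  expect_error(library_spec(states = "x", trig_vars = "y"), "subset")
})

test_that("evaluation matches closed forms and a pointwise oracle", {
  data <- cbind(x = 3, dx = 0.5, phi = pi / 4)
  spec <- library_spec(states = c("x", "phi"), derivs = c("dx", "dphi"),
                       degree = 2, trig_vars = "phi", deriv_vars = "dx")
  lib <- build_library(rbind(data, data), spec)
  expect_equal(unname(lib$values[1, match("x^2", lib$labels)]), 9)
  expect_equal(unname(lib$values[1, match("x*dx", lib$labels)]), 1.5)
  expect_equal(unname(lib$values[1, match("sin(phi)*cos(phi)", lib$labels)]), 0.5)

  # property: random samples and terms up to degree 4 agree with
  # direct pointwise arithmetic
  spec4 <- library_spec(states = c("x", "y"), derivs = c("dx", "dy"),
                        degree = 4, trig_vars = "y", deriv_vars = "dx")
  terms <- enumerate_terms(spec4)
  vars <- withr::with_seed(11, cbind(x = rnorm(100), y = rnorm(100),
                                     dx = rnorm(100)))
  lib4 <- evaluate_terms(terms, vars)
  for (j in seq_along(terms)) {
    direct <- vapply(seq_len(100), function(i)
      eval_term_pointwise(terms[[j]], as.list(vars[i, ])), 0)
    expect_equal(lib4$values[, j], direct, tolerance = 1e-12)
  }
})

test_that("evaluation errors on missing variables", {
  spec <- library_spec(states = "x", degree = 1, deriv_vars = "dx")
  terms <- enumerate_terms(spec)
  expect_error(evaluate_terms(terms, cbind(x = 1:5)), "dx")
})

test_that("split_candidate removes and restores columns faithfully", {
  vars <- withr::with_seed(2, cbind(x = runif(20, 0.2, 2), dx = rnorm(20)))
  lib <- build_library(vars, mm_library_spec())
  p <- length(lib$labels)
  sp <- split_candidate(lib, 3)
  expect_length(sp$reduced$labels, p - 1)
  expect_identical(sp$reduced$labels, lib$labels[-3])
  # round-trip: re-inserting the column reproduces the original matrix
  rebuilt <- cbind(sp$reduced$values[, 1:2], sp$lhs, sp$reduced$values[, 3:5])
  expect_equal(unname(rebuilt), unname(lib$values))
  expect_error(split_candidate(lib, p + 1), "range")
})

test_that("degenerate one-column libraries are rejected downstream", {
  vars <- cbind(x = runif(10))
  lib <- evaluate_terms(enumerate_terms(
    library_spec(states = "x", degree = 1, deriv_vars = character(),
                 include_constant = FALSE)), vars)
  sp <- split_candidate(lib, 1)
  expect_length(sp$reduced$labels, 0)
  expect_error(stlsq(sp$reduced$values, sp$lhs, 0.1), "column")
})

test_that("column normalization stores norms and flags zero columns", {
  lib <- structure(list(
    values = cbind(a = c(3, 4), b = c(0, 0)),
    terms = list(new_term_for_test("a"), new_term_for_test("b")),
    labels = c("a", "b"), norms = NULL, zero = c(FALSE, TRUE),
    spec = NULL), class = "library_matrix")
  nl <- normalize_columns(lib)
  expect_equal(nl$norms, c(a = 5, b = 0))
  expect_equal(unname(nl$values[, 1]), c(0.6, 0.8))
  expect_equal(unname(nl$values[, 2]), c(0, 0))  # untouched
})

test_that("coefficients found on normalized columns match the raw fit", {
  set.seed(31)
  A <- matrix(rnorm(100), 20, 5) %*% diag(c(10, 1, 0.1, 5, 0.01))
  colnames(A) <- paste0("c", 1:5)
  b <- A %*% c(1, -2, 3, 0, 0)
  f_norm <- stlsq(A, b, 1e-8, normalize = TRUE, ridge = 0)
  f_raw <- stlsq(A, b, 1e-10, normalize = FALSE, ridge = 0)
  expect_equal(f_norm$coef, f_raw$coef, tolerance = 1e-10)
})
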