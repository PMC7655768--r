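make_split_mm <- function(spec = mm_unique_spec()) {
  # train on one transient, validate on another: both blocks then
  # carry derivative signal (the tail of a single long run sits at the
  # fixed point, where relative errors are dominated by round-off)
  train <- simulate_michaelis_menten(x0 = 0.5, times = seq(0, 2.5, by = 0.01))
  test <- simulate_michaelis_menten(x0 = 1.2, times = seq(0, 2, by = 0.01))
  list(train = build_library(train, spec),
       test = test,
       test_lib = build_library(test, spec))
}

test_that("model-fit error behaves like a relative residual", {
  s <- make_split_mm()
  good <- fit_candidate(s$train, "x*dx", 0.1)
  expect_lt(fit_error(good, s$test_lib), 1e-6)
  zero <- good
  zero$coef[] <- 0
  expect_equal(fit_error(zero, s$test_lib), 1)
  # invariance to a common rescaling of all library columns
  scaled <- s$test_lib
  scaled$values <- scaled$values * 10
  expect_equal(fit_error(good, scaled), fit_error(good, s$test_lib),
               tolerance = 1e-9)
})

test_that("predicted-derivative error scores the explicit form", {
  s <- make_split_mm()
  ode <- to_explicit_ode(fit_candidate(s$train, "x*dx", 0.1))
  expect_lt(derivative_error(ode, s$test), 1e-6)
  zero_ode <- ode
  zero_ode$num$coef[] <- 0
  expect_equal(as.numeric(derivative_error(zero_ode, s$test)), 1)
})

test_that("noise on the validation derivatives raises the true model's error to the noise-to-signal ratio", {
  data <- simulate_michaelis_menten(x0 = 1.5, times = seq(0, 2, by = 1e-3))
  lib <- build_library(data, mm_library_spec())
  ode <- to_explicit_ode(fit_candidate(lib, "x*dx", 0.1))
  sig <- 0.05
  errs <- vapply(1:20, function(s) {
    noisy <- add_noise(data, sig, seed = s, channels = "derivs")
    as.numeric(derivative_error(ode, noisy))
  }, 0)
  expected <- sig / sqrt(mean(data$Xdot^2))
  expect_equal(mean(errs), expected, tolerance = 0.1)
})

test_that("selection returns the lowest-error candidate and tolerates failures", {
  s <- make_split_mm()
  models <- sweep_candidates(s$train, lambdas = seq(0.1, 1, by = 0.1))
  rep <- select_model(models, criterion = "derivative", test_data = s$test)
  expect_s3_class(rep, "selection_report")
  best <- which.min(rep$table$error)
  expect_equal(rep$table$error[rep$winner_index], rep$table$error[best])
  # a single candidate wins trivially
  one <- select_model(models[1], criterion = "derivative", test_data = s$test)
  expect_identical(one$winner_index, 1L)
})

test_that("permuting candidate order moves the winner only among equivalent models", {
  s <- make_split_mm()
  models <- sweep_candidates(s$train, lambdas = seq(0.1, 1, by = 0.1))
  rep1 <- select_model(models, criterion = "derivative", test_data = s$test,
                       prefer_consistency = TRUE)
  perm <- withr::with_seed(9, sample(length(models)))
  rep2 <- select_model(models[perm], criterion = "derivative",
                       test_data = s$test, prefer_consistency = TRUE)
  expect_identical(implicit_support(rep1$winner),
                   implicit_support(rep2$winner))
})

test_that("cross-referencing groups candidates that rediscover the same relation", {
  s <- make_split_mm()
  models <- sweep_candidates(s$train, lambdas = seq(0.1, 1, by = 0.1))
  gr <- cross_reference(models)
  # the base relation is reachable from several lhs choices
  big <- models[gr$largest]
  expect_gt(length(gr$largest), 1)
  supports <- unique(lapply(big, implicit_support))
  expect_length(supports, 1)
  # duplicated candidate list collapses into one group
  dup <- models[c(9, 9, 9)]
  gdup <- cross_reference(dup)
  expect_length(gdup$groups, 1)
  expect_length(gdup$largest, 3)
})

test_that("the pipeline selects the base enzyme-kinetics relation end to end", {
  data <- mm_quick_data()
  rep <- sindy_pi(data, mm_library_spec())
  expect_equal(structure_error(rep$winner, mm_truth_support())$total, 0)
  expect_s3_class(rep$winner_ode, "rational_ode")
})

test_that("an 80/20 chronological split preserves order and proportions", {
  data <- mm_quick_data()
  parts <- split_ts_data(data, 0.8)
  m <- nrow(data$X)
  expect_equal(nrow(parts$train$X), floor(0.8 * m))
  expect_lt(max(parts$train$t), min(parts$test$t))
})
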