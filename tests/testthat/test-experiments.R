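tiny_noise_config <- function(out_dir, seed = 5) {
  list(experiment = "noise", out_dir = out_dir,
       noise_grid = c(1e-8, 1e-2), reps = 2, T = 1, seed = seed)
}

test_that("benchmarks honour their repetition bookkeeping", {
  b <- noise_robustness_benchmark(noise_grid = c(1e-8, 1e-2), reps = 2,
                                  T = 1, seed = 5)
  expect_equal(nrow(b$records), 2 * 2 * 2)   # levels x reps x methods
  counts <- table(b$records$method, b$records$noise)
  expect_true(all(counts == 2))
  expect_identical(b$records$success,
                   !is.na(b$records$structure_error) &
                     b$records$structure_error == 0)
})

test_that("benchmarks are pure functions of their seeds", {
  b1 <- noise_robustness_benchmark(noise_grid = 1e-8, reps = 2, T = 1, seed = 9)
  b2 <- noise_robustness_benchmark(noise_grid = 1e-8, reps = 2, T = 1, seed = 9)
  expect_identical(b1$records, b2$records)
  d1 <- data_efficiency_benchmark(fractions = 0.5, reps = 2, n_traj = 2,
                                  T = 2, seed = 9)
  d2 <- data_efficiency_benchmark(fractions = 0.5, reps = 2, n_traj = 2,
                                  T = 2, seed = 9)
  expect_identical(d1$records, d2$records)
})

test_that("the data benchmark validates its fraction grid", {
  expect_error(data_efficiency_benchmark(fractions = c(0.5, 1.5)), "fractions")
  expect_error(data_efficiency_benchmark(fractions = 0), "fractions")
})

test_that("run_experiment writes deterministic artifacts", {
  d1 <- file.path(tempdir(), "exp1"); d2 <- file.path(tempdir(), "exp2")
  run_experiment(tiny_noise_config(d1))
  run_experiment(tiny_noise_config(d2))
  expect_identical(readLines(file.path(d1, "records.tsv")),
                   readLines(file.path(d2, "records.tsv")))
  expect_true(file.exists(file.path(d1, "summary.tsv")))
  expect_true(file.exists(file.path(d1, "log.txt")))
})

test_that("experiment configs are validated before running", {
  expect_error(run_experiment(list(experiment = "simulate",
                                   out_dir = tempdir())),
               "missing keys: system")
  expect_error(run_experiment(list(experiment = "nonsense",
                                   out_dir = tempdir())), "unknown experiment")
  # dry run validates and writes nothing
  d3 <- file.path(tempdir(), "dry_run_out")
  cfg <- tiny_noise_config(d3)
  run_experiment(cfg, dry_run = TRUE)
  expect_false(dir.exists(d3))
})

test_that("experiment configs round-trip through YAML files", {
  d4 <- file.path(tempdir(), "exp_yaml")
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(experiment = "simulate", system = "mm",
                        out_dir = d4, x0 = 0.5,
                        times = seq(0, 1, by = 0.01)), path)
  run_experiment(path)
  traj <- read_ts_data(file.path(d4, "trajectory.tsv"),
                       states = "x", derivs = "dx")
  expect_equal(nrow(traj$X), 101)
  expect_equal(traj$X[1, "x"], c(x = 0.5))
})

test_that("models serialize to text losslessly", {
  data <- mm_quick_data()
  lib <- build_library(data, mm_library_spec())
  m <- fit_candidate(lib, "x*dx", 0.1)
  path <- tempfile(fileext = ".txt")
  serialize_model(m, path)
  m2 <- load_model(path, vocabulary = lib$labels)
  expect_identical(m2$lhs_label, m$lhs_label)
  expect_identical(m2$lambda, m$lambda)
  expect_identical(m2$coef[names(m2$coef)], m$coef[m$coef != 0])  # full precision
  # unknown labels and version mismatches are errors
  expect_error(load_model(path, vocabulary = c("1", "x")), "unknown term")
  lines <- readLines(path)
  lines[1] <- "sindypi_model: 99"
  writeLines(lines, path)
  expect_error(load_model(path), "version mismatch")
})

test_that("trajectories round-trip through delimited text", {
  data <- simulate_cart_pendulum(times = seq(0, 0.5, by = 0.01))
  path <- tempfile(fileext = ".tsv")
  write_ts_data(data, path)
  back <- read_ts_data(path, states = colnames(data$X),
                       derivs = colnames(data$Xdot), controls = "F")
  expect_equal(back$X, data$X, tolerance = 1e-12)
  expect_equal(back$Xdot, data$Xdot, tolerance = 1e-12)
  expect_equal(back$U, data$U, tolerance = 1e-12)
})
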