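# PDE identification: flatten space-time fields into regression
# samples, build implicit libraries including u_t-bearing terms, fit
# with the candidate-sweep machinery, and provide the explicit
# regression baseline that lacks rational terms.

# Flatten a named list of nx x nt field matrices into a sample x
# variable matrix. `time_idx` selects time slices; `trim_time` drops
# slices near the (non-periodic) time boundaries where
# finite-difference time derivatives are unreliable.
flatten_fields <- function(fields, time_idx = NULL, trim_time = 0) {
  nt <- ncol(fields[[1]])
  if (is.null(time_idx)) time_idx <- seq_len(nt)
  if (trim_time > 0)
    time_idx <- setdiff(time_idx, c(seq_len(trim_time),
                                    (nt - trim_time + 1L):nt))
  if (length(time_idx) == 0) stop("no time slices left after trimming")
  out <- vapply(fields, function(m) as.numeric(m[, time_idx, drop = FALSE]),
                numeric(nrow(fields[[1]]) * length(time_idx)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1)
  colnames(out) <- names(fields)
  out
}

#' Build a PDE candidate library from space-time fields
#'
#' Flattens the supplied variable fields (the state, its spatial
#' derivatives, and optionally its time derivative) into samples and
#' evaluates the term vocabulary of `spec` on them. A seeded uniform
#' subsample keeps the regression at desk scale regardless of grid
#' resolution.
#'
#' @param fields named list of nx x nt matrices (e.g. from
#'   [kdv_variables()]); names are the variable names the spec refers
#'   to.
#' @param spec a [library_spec()].
#' @param subsample number of space-time samples to draw (NULL = all).
#' @param seed seed for the subsample.
#' @param trim_time drop this many time slices at each end before
#'   sampling (use when time derivatives come from finite differences
#'   near a non-periodic boundary; default 0).
#' @param time_idx optional explicit subset of time-slice indices.
#' @return A `library_matrix`; attribute `rows` records how many
#'   samples were available and used.
#' @export
build_pde_library <- function(fields, spec, subsample = NULL, seed = 1,
                              trim_time = 0, time_idx = NULL) {
  vars <- flatten_fields(fields, time_idx = time_idx, trim_time = trim_time)
  avail <- nrow(vars)
  if (!is.null(subsample) && subsample < avail) {
    pick <- with_seed(seed, sort(sample.int(avail, subsample)))
    vars <- vars[pick, , drop = FALSE]
  }
  lib <- build_library(vars, spec)
  attr(lib, "rows") <- c(available = avail, used = nrow(vars))
  lib
}

#' Implicit PDE identification (candidate sweep on field data)
#'
#' Splits the time axis chronologically, builds the implicit library
#' on the training block, sweeps the candidate left-hand sides over
#' the threshold grid, and selects by predicted-u_t error on the
#' validation block. The winner is returned in explicit rational form
#' u_t = N / D.
#'
#' @param fields named list of variable fields including the time
#'   derivative (see [kdv_variables()]).
#' @param spec implicit [library_spec()] (must include the time
#'   derivative among its derivative variables).
#' @param candidates candidate lhs labels (default u_t and u_t * u
#'   products present in the vocabulary).
#' @param lambdas threshold grid.
#' @param deriv_var name of the time-derivative variable (default
#'   "u_t").
#' @param train_frac chronological training fraction (default 0.8).
#' @param subsample training-sample cap (default 5000).
#' @param seed subsampling seed.
#' @param prefer_consistency resolve near-ties by cross-reference
#'   consensus (see [select_model()]); default TRUE.
#' @param ... passed to [stlsq()].
#' @return A `selection_report` with the winning `candidate_model`,
#'   its `winner_ode` (rational PDE), and the scored table.
#' @export
fit_pde_implicit <- function(fields, spec, candidates = NULL,
                             lambdas = 10^seq(-4, 0, by = 0.25),
                             deriv_var = "u_t", train_frac = 0.8,
                             subsample = 5000, seed = 1,
                             prefer_consistency = TRUE, ...) {
  if (!deriv_var %in% names(fields))
    stop(sprintf("fields must include the time derivative '%s'", deriv_var))
  if (!deriv_var %in% spec$deriv_vars)
    stop("library spec must list the time derivative among deriv_vars when fitting implicitly")
  if (!is.null(candidates) && length(candidates) == 0)
    stop("empty candidate set")
  nt <- ncol(fields[[1]])
  ntr <- max(2L, floor(nt * train_frac))
  if (ntr >= nt) stop("train fraction leaves no validation slices")
  train_lib <- build_pde_library(fields, spec, subsample = subsample,
                                 seed = seed, time_idx = seq_len(ntr))
  val_vars <- flatten_fields(fields, time_idx = (ntr + 1L):nt)
  if (!is.null(subsample) && subsample < nrow(val_vars)) {
    pick <- with_seed(seed + 1L, sort(sample.int(nrow(val_vars), subsample)))
    val_vars <- val_vars[pick, , drop = FALSE]
  }
  models <- sweep_candidates(train_lib, candidates, lambdas, ...)
  report <- select_model(models, criterion = "derivative",
                         test_vars = val_vars,
                         prefer_consistency = prefer_consistency)
  report$models <- models
  report$groups <- cross_reference(models)
  report
}

#' Explicit PDE regression baseline
#'
#' Regresses u_t directly onto a library of explicit terms (no
#' u_t-bearing columns), the standard sparse PDE discovery approach.
#' It cannot represent rational dynamics: when a denominator term is
#' active in the truth, the baseline can only compensate by distorting
#' or inflating the explicit terms. Threshold selection uses the
#' validation residual on the held-out time block.
#'
#' @param fields named list of variable fields including `deriv_var`.
#' @param spec explicit [library_spec()]; any term referencing
#'   `deriv_var` is rejected (that would leak the target into the
#'   regressors).
#' @param lambdas threshold grid.
#' @param deriv_var time-derivative variable regressed on the library.
#' @inheritParams fit_pde_implicit
#' @return list with `coef` (named, winning threshold), `support`
#'   labels, `lambda`, validation `error`, and the per-lambda `table`.
#' @export
pdefind_baseline <- function(fields, spec, lambdas = 10^seq(-4, 0, by = 0.25),
                             deriv_var = "u_t", train_frac = 0.8,
                             subsample = 5000, seed = 1, ...) {
  terms <- enumerate_terms(spec)
  leaks <- vapply(terms, function(tm) deriv_var %in% names(tm$powers), TRUE)
  if (any(leaks))
    stop("explicit baseline library must not contain the regression target ",
         deriv_var)
  if (!deriv_var %in% names(fields))
    stop(sprintf("fields must include '%s'", deriv_var))
  nt <- ncol(fields[[1]])
  ntr <- max(2L, floor(nt * train_frac))
  train_vars <- flatten_fields(fields, time_idx = seq_len(ntr))
  if (!is.null(subsample) && subsample < nrow(train_vars)) {
    pick <- with_seed(seed, sort(sample.int(nrow(train_vars), subsample)))
    train_vars <- train_vars[pick, , drop = FALSE]
  }
  val_vars <- flatten_fields(fields, time_idx = (ntr + 1L):nt)
  A <- evaluate_terms(terms, train_vars, spec = spec)
  b <- train_vars[, deriv_var]
  Av <- evaluate_terms(terms, val_vars, spec = spec)
  bv <- val_vars[, deriv_var]
  bvn <- sqrt(sum(bv^2))
  tab <- data.frame(lambda = lambdas, error = NA_real_,
                    sparsity = NA_integer_)
  fits <- vector("list", length(lambdas))
  for (i in seq_along(lambdas)) {
    fit <- stlsq(A$values, b, lambdas[i], ...)
    fits[[i]] <- fit
    tab$sparsity[i] <- sum(fit$support)
    if (!fit$empty_model)
      tab$error[i] <- sqrt(sum((bv - Av$values %*% fit$coef)^2)) / bvn
  }
  ok <- which(is.finite(tab$error))
  if (length(ok) == 0) stop("all thresholds produced empty models")
  emin <- min(tab$error[ok])
  ties <- ok[tab$error[ok] <= emin + 1e-12 * max(emin, 1e-300)]
  best <- ties[order(tab$sparsity[ties], ties)][1]
  fit <- fits[[best]]
  list(coef = fit$coef[fit$support],
       support = sort(names(fit$coef)[fit$support]),
       lambda = lambdas[best], error = tab$error[best], table = tab,
       fit = fit)
}
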