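#' Model-fit validation error
#'
#' Relative residual of the fitted implicit relation on held-out data:
#' || theta_j(test) - Theta'(test) xi_j ||_2 / || theta_j(test) ||_2.
#' Invariant to a common rescaling of all library columns and equal to
#' exactly 1 for the all-zero coefficient vector.
#'
#' @param model a `candidate_model`.
#' @param test_lib a `library_matrix` built on test data with the same
#'   specification (labels must match).
#' @export
fit_error <- function(model, test_lib) {
  stopifnot(inherits(model, "candidate_model"),
            inherits(test_lib, "library_matrix"))
  if (!is.null(test_lib$norms))
    stop("fit_error expects an un-normalized test library")
  j <- match(model$lhs_label, test_lib$labels)
  if (is.na(j)) stop("lhs term not present in test library")
  b <- test_lib$values[, j]
  bn <- sqrt(sum(b^2))
  if (bn == 0) stop("zero-norm lhs on test data")
  rhs <- match(names(model$coef), test_lib$labels)
  if (any(is.na(rhs))) stop("test library is missing model terms")
  pred <- test_lib$values[, rhs, drop = FALSE] %*% model$coef
  sqrt(sum((b - pred)^2)) / bn
}

# predicted-derivative error of one rational ODE on a named variable
# matrix holding states (+controls) and the measured derivative target.
rational_prediction <- function(ode, vars, eps_d = 1e-8) {
  num <- eval_term_sum(ode$num$terms, ode$num$coef, vars)
  den <- eval_term_sum(ode$den$terms, ode$den$coef, vars)
  guard <- eps_d * max(abs(den), 1e-300)
  ok <- abs(den) >= guard
  list(pred = ifelse(ok, num / ifelse(ok, den, 1), NA_real_), ok = ok)
}

#' Predicted-derivative validation error
#'
#' || Xdot_test - Xdot_model ||_2 / || Xdot_test ||_2 with the model
#' derivative N(x)/D(x) evaluated on the test states. This is the
#' criterion of choice for rational dynamics: it scores the explicit
#' form the user ultimately cares about. Samples where |D| falls below
#' the safeguard are excluded and counted.
#'
#' @param odes a `rational_ode` or list of them.
#' @param test_data a `ts_data` with derivatives.
#' @param eps_d relative denominator safeguard (default 1e-8).
#' @return numeric error with attribute `excluded` (samples dropped by
#'   the denominator guard).
#' @export
derivative_error <- function(odes, test_data, eps_d = 1e-8) {
  if (inherits(odes, "rational_ode")) odes <- list(odes)
  stopifnot(inherits(test_data, "ts_data"))
  if (is.null(test_data$Xdot)) stop("test data must include derivatives")
  vars <- ts_variables(test_data)
  err2 <- 0; ref2 <- 0; excluded <- 0L
  for (ode in odes) {
    target <- vars[, ode$deriv_var]
    rp <- rational_prediction(ode, vars, eps_d)
    excluded <- excluded + sum(!rp$ok)
    err2 <- err2 + sum((target[rp$ok] - rp$pred[rp$ok])^2)
    ref2 <- ref2 + sum(target[rp$ok]^2)
  }
  if (ref2 == 0) stop("zero-norm derivative target on test data")
  out <- sqrt(err2) / sqrt(ref2)
  attr(out, "excluded") <- excluded
  out
}

#' Select the best candidate model on held-out data
#'
#' Scores every candidate model on validation data and returns the one
#' with the smallest error; ties are broken by smaller support, then by
#' candidate order. The full per-candidate, per-lambda table is
#' retained for audit.
#'
#' @param models list of `candidate_model` objects (failed entries of
#'   class `candidate_failure` are tabulated, not scored).
#' @param criterion `"derivative"` (predicted-derivative error, the
#'   default for rational dynamics) or `"fit"` (implicit model fit).
#' @param test_data a `ts_data` with derivatives (derivative
#'   criterion), or NULL when `test_vars` is given.
#' @param test_lib un-normalized `library_matrix` on test data (fit
#'   criterion).
#' @param test_vars optional named variable matrix replacing
#'   `test_data` (must contain state and derivative columns).
#' @param eps_d denominator safeguard for the derivative criterion.
#' @param prefer_consistency resolve near-optimal models by
#'   cross-reference: among models whose error is within
#'   `consistency_window` times the best, prefer the implicit support
#'   rediscovered by the most distinct candidate left-hand sides (see
#'   Details), then pick the lowest-error model of that support.
#'   Default FALSE (plain argmin).
#' @param consistency_window multiplicative error window defining the
#'   near-optimal set (default 3).
#' @details Implicit relations are only defined up to multiplication
#'   by a library term, so several structurally different supports can
#'   encode the same rational dynamics and tie (up to numerical noise)
#'   on any validation criterion. Redundancy across candidate
#'   left-hand sides breaks the tie: every term of the true relation
#'   serves as a working candidate and rediscovers the same support,
#'   while its term-multiples are reachable from fewer candidates.
#' @return An object of class `selection_report`: `table`
#'   (data.frame), `winner`, `winner_ode` (derivative criterion),
#'   `criterion`.
#' @export
select_model <- function(models, criterion = c("derivative", "fit"),
                         test_data = NULL, test_lib = NULL,
                         test_vars = NULL, eps_d = 1e-8,
                         prefer_consistency = FALSE,
                         consistency_window = 3) {
  criterion <- match.arg(criterion)
  if (criterion == "derivative") {
    if (is.null(test_vars)) {
      stopifnot(inherits(test_data, "ts_data"))
      if (is.null(test_data$Xdot)) stop("test data must include derivatives")
      test_vars <- ts_variables(test_data)
    }
  } else if (is.null(test_lib)) {
    stop("fit criterion requires test_lib")
  }
  n <- length(models)
  if (n == 0) stop("no candidate models supplied")
  err <- rep(NA_real_, n)
  odes <- vector("list", n)
  lhs <- character(n); lam <- numeric(n); spars <- rep(NA_integer_, n)
  note <- character(n)
  for (i in seq_len(n)) {
    m <- models[[i]]
    lhs[i] <- m$lhs_label %||% NA_character_
    lam[i] <- m$lambda %||% NA_real_
    if (inherits(m, "candidate_failure")) {
      note[i] <- m$message
      next
    }
    spars[i] <- m$sparsity
    if (m$empty_model) {
      note[i] <- "empty model"
      next
    }
    res <- tryCatch({
      if (criterion == "fit") {
        list(err = fit_error(m, test_lib), ode = NULL)
      } else {
        ode <- to_explicit_ode(m)
        target <- test_vars[, ode$deriv_var]
        rp <- rational_prediction(ode, test_vars, eps_d)
        if (!any(rp$ok)) stop("denominator safeguard excluded all test samples")
        tn <- sqrt(sum(target[rp$ok]^2))
        if (tn == 0) stop("zero-norm derivative target")
        list(err = sqrt(sum((target[rp$ok] - rp$pred[rp$ok])^2)) / tn,
             ode = ode)
      }
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      note[i] <- res
    } else {
      err[i] <- res$err
      odes[[i]] <- res$ode
    }
  }
  tab <- data.frame(candidate = lhs, lambda = lam, error = err,
                    sparsity = spars, note = note,
                    stringsAsFactors = FALSE)
  ok <- which(is.finite(err))
  if (length(ok) == 0) stop("all candidate models failed validation")
  emin <- min(err[ok])
  if (prefer_consistency) {
    near <- ok[err[ok] <= consistency_window * emin + 1e-300]
    keys <- vapply(models[near], function(m)
      paste(implicit_support(m), collapse = " | "), "")
    grp <- split(near, keys)
    # among near-optimal models: smallest implicit support first (an
    # accurate sparser relation beats a denser one whose validation
    # error is statistically indistinguishable), then the support
    # rediscovered by the most candidate lhs choices, then sweep order
    size <- vapply(grp, function(ix) 1L + spars[ix[1]], 0L)
    n_cand <- vapply(grp, function(ix) length(unique(lhs[ix])), 0L)
    first <- vapply(grp, min, 0L)
    best_grp <- grp[[order(size, -n_cand, -lengths(grp), first)[1]]]
    # family reduction: if a near-optimal group's support is the
    # chosen support divided by a common monomial factor, the two
    # encode the same rational dynamics; report the common-factor-free
    # (lowest-degree) representative
    chosen <- models[[best_grp[1]]]
    best_deg <- support_degree(chosen)
    for (g in grp) {
      cand <- models[[g[1]]]
      if (support_degree(cand) < best_deg &&
          is_support_multiple(cand, chosen)) {
        best_grp <- g
        best_deg <- support_degree(cand)
      }
    }
    ok <- best_grp
    emin <- min(err[ok])
  }
  ties <- ok[err[ok] <= emin + 1e-12 * max(emin, 1e-300)]
  ties <- ties[order(spars[ties], ties)]
  win <- ties[1]
  structure(list(table = tab, winner = models[[win]],
                 winner_index = win, winner_ode = odes[[win]],
                 criterion = criterion),
            class = "selection_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.selection_report <- function(x, ...) {
  w <- x$winner
  cat(sprintf("<selection_report> criterion = %s; %d models scored\n",
              x$criterion, nrow(x$table)))
  cat(sprintf("  winner: lhs = %s, lambda = %g, error = %.4g, %d terms\n",
              w$lhs_label, w$lambda, x$table$error[x$winner_index],
              w$sparsity))
  invisible(x)
}

#' Cross-reference candidate models by implicit support
#'
#' Correct candidate left-hand sides all re-discover the same implicit
#' relation, so their models share one sparsity pattern; incorrect
#' candidates scatter. Groups models whose implicit supports coincide
#' and reports the groups by decreasing size.
#'
#' @param models list of candidate models (failures ignored).
#' @return An object of class `consistency_groups`: list `groups` of
#'   index vectors into `models`, the shared `supports`, and
#'   `largest` (indices of the biggest group).
#' @export
cross_reference <- function(models) {
  idx <- which(vapply(models, inherits, TRUE, what = "candidate_model"))
  idx <- idx[!vapply(models[idx], `[[`, TRUE, "empty_model")]
  if (length(idx) == 0)
    return(structure(list(groups = list(), supports = character(),
                          largest = integer()), class = "consistency_groups"))
  keys <- vapply(models[idx], function(m)
    paste(implicit_support(m), collapse = " | "), "")
  gr <- split(idx, keys)
  ord <- order(-lengths(gr), vapply(gr, min, 1L))
  gr <- gr[ord]
  structure(list(groups = gr, supports = names(gr),
                 largest = gr[[1]]), class = "consistency_groups")
}

#' @export
print.consistency_groups <- function(x, ...) {
  cat(sprintf("<consistency_groups> %d groups; largest has %d models\n",
              length(x$groups), length(x$largest)))
  invisible(x)
}

#' Parallel implicit identification pipeline
#'
#' The full workflow: split the data chronologically into training and
#' validation blocks, build the candidate library on each, sweep
#' candidate left-hand sides over a threshold grid, score every model
#' on the validation block, and return the winner together with its
#' explicit rational form and the cross-reference of candidate
#' supports.
#'
#' @param data a `ts_data` with derivatives.
#' @param spec a [library_spec()].
#' @param test optional held-out `ts_data`; if NULL, `data` is split
#'   chronologically by `train_frac` (default 80/20).
#' @param candidates candidate lhs labels; default: all
#'   derivative-bearing terms.
#' @param lambdas threshold grid (default 0.1 to 1 in steps of 0.1).
#' @param criterion `"derivative"` or `"fit"`.
#' @param train_frac training fraction for the chronological split.
#' @param prefer_consistency resolve near-ties by cross-reference
#'   consensus (see [select_model()]); default TRUE.
#' @param ... passed to [stlsq()].
#' @return A `selection_report` with additional fields `models` and
#'   `groups`.
#' @export
sindy_pi <- function(data, spec, test = NULL, candidates = NULL,
                     lambdas = seq(0.1, 1, by = 0.1),
                     criterion = c("derivative", "fit"),
                     train_frac = 0.8, prefer_consistency = TRUE, ...) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(data, "ts_data"), inherits(spec, "library_spec"))
  if (is.null(test)) {
    parts <- split_ts_data(data, train_frac)
    train <- parts$train
    test <- parts$test
  } else {
    train <- data
  }
  train_lib <- build_library(train, spec)
  models <- sweep_candidates(train_lib, candidates, lambdas, ...)
  report <- select_model(models, criterion = criterion,
                         test_data = test,
                         test_lib = if (criterion == "fit")
                           build_library(test, spec),
                         prefer_consistency = prefer_consistency)
  report$models <- models
  report$groups <- cross_reference(models)
  report
}
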