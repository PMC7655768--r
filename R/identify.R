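#' Fit a sparse model for one candidate left-hand side
#'
#' Treats library column j as if it were known, regresses it on the
#' remaining columns with sequentially thresholded least squares, and
#' wraps the result as a candidate implicit model. A correct candidate
#' (a term that really appears in the dynamics) yields a sparse and
#' accurate fit; an incorrect one yields a dense and/or inaccurate fit,
#' which is what model selection exploits.
#'
#' @param lib a `library_matrix` evaluated on training data.
#' @param j candidate column index or term label.
#' @param lambda threshold for [stlsq()].
#' @param ... further arguments to [stlsq()].
#' @return An object of class `candidate_model`.
#' @export
fit_candidate <- function(lib, j, lambda, ...) {
  sp <- split_candidate(lib, j)
  if (all(sp$lhs == 0)) stop("degenerate lhs: candidate column is identically zero on the data")
  fit <- stlsq(sp$reduced$values, sp$lhs, lambda, ...)
  structure(list(
    lhs_term = sp$lhs_term, lhs_label = sp$lhs_label,
    coef = fit$coef, lambda = lambda,
    residual = fit$relative_residual,
    sparsity = sum(fit$support),
    empty_model = fit$empty_model,
    rhs_terms = sp$reduced$terms,
    spec = lib$spec,
    fit = fit,
    diagnostics = list()
  ), class = "candidate_model")
}

#' @export
print.candidate_model <- function(x, ...) {
  cat(sprintf("<candidate_model> lhs = %s, lambda = %g, %d active terms, rel. residual = %.3g\n",
              x$lhs_label, x$lambda, x$sparsity, x$residual))
  cf <- x$coef[x$coef != 0]
  for (i in seq_along(cf))
    cat(sprintf("  %-24s %+.6g\n", names(cf)[i], cf[i]))
  invisible(x)
}

#' Implicit support of a candidate model
#'
#' Term labels of the implicit relation the model encodes: the
#' candidate left-hand side plus the active right-hand-side terms.
#' Supports are compared after scale normalization, so the labels are
#' all that matters.
#' @param model a `candidate_model`.
#' @export
implicit_support <- function(model) {
  stopifnot(inherits(model, "candidate_model"))
  sort(c(model$lhs_label, names(model$coef)[model$coef != 0]))
}

# total degree of the implicit relation (sum of term degrees over the
# support): the common-factor-free representation of a rational
# dynamics has the lowest total degree among its term-multiples
support_degree <- function(model) {
  sum(vapply(support_terms(model), function(tm) sum(tm$powers), 0))
}

# term descriptors of the implicit support (lhs + active rhs terms)
support_terms <- function(model) {
  c(list(model$lhs_term), model$rhs_terms[model$coef != 0])
}

# TRUE when modelB's support equals modelA's support multiplied by one
# non-constant monomial: the two supports then encode the same
# rational dynamics, and A is the lower-degree representative
is_support_multiple <- function(modelA, modelB) {
  ta <- support_terms(modelA)
  tb <- support_terms(modelB)
  if (length(ta) != length(tb)) return(FALSE)
  merge_pows <- function(p, q, sgn = 1) {
    nms <- union(names(p), names(q))
    out <- stats::setNames(numeric(length(nms)), nms)
    out[names(p)] <- p
    out[names(q)] <- out[names(q)] + sgn * q
    out
  }
  deg <- function(tm) sum(tm$powers)
  pkey <- function(p) {
    p <- p[p != 0]
    paste(sort(paste0(names(p), "^", p)), collapse = "*")
  }
  a0 <- ta[[which.min(vapply(ta, deg, 0))]]
  key_b <- sort(vapply(tb, function(tm) pkey(tm$powers), ""))
  for (b in tb) {
    m <- merge_pows(b$powers, a0$powers, sgn = -1)
    if (any(m < 0) || all(m == 0)) next
    mapped <- sort(vapply(ta, function(tm)
      pkey(merge_pows(tm$powers, m)), ""))
    if (identical(mapped, key_b)) return(TRUE)
  }
  FALSE
}

# default candidate set: derivative-bearing terms (the x_k-dot * theta(x)
# restriction that makes models convertible to rational form)
derivative_candidates <- function(lib, deriv_vars = lib$spec$deriv_vars) {
  if (is.null(deriv_vars)) stop("no derivative variables known; pass candidates explicitly")
  has_deriv <- vapply(lib$terms, function(tm)
    any(names(tm$powers) %in% deriv_vars), TRUE)
  lib$labels[has_deriv & !lib$zero]
}

#' Sweep candidate left-hand sides over a threshold grid
#'
#' Fits one sparse model per (candidate, lambda) pair. The sweep is a
#' pure map: results are deterministic and independent of execution
#' order. Per-fit errors are captured and recorded rather than
#' aborting the sweep.
#'
#' @param lib a `library_matrix` on training data.
#' @param candidates candidate column labels/indices; default: every
#'   derivative-bearing library term.
#' @param lambdas numeric vector of thresholds.
#' @param ... passed to [fit_candidate()].
#' @return list of `candidate_model` objects (failed fits appear as
#'   entries of class `candidate_failure`), ordered candidate-major.
#' @export
sweep_candidates <- function(lib, candidates = NULL, lambdas = seq(0.1, 1, by = 0.1),
                             ...) {
  stopifnot(inherits(lib, "library_matrix"))
  if (is.null(candidates)) candidates <- derivative_candidates(lib)
  if (length(candidates) == 0) stop("empty candidate set")
  out <- vector("list", length(candidates) * length(lambdas))
  i <- 0L
  for (cand in candidates) {
    for (lam in lambdas) {
      i <- i + 1L
      out[[i]] <- tryCatch(fit_candidate(lib, cand, lam, ...),
                           error = function(e) structure(
                             list(lhs_label = as.character(cand), lambda = lam,
                                  message = conditionMessage(e)),
                             class = "candidate_failure"))
    }
  }
  out
}

#' Convert an implicit candidate model to an explicit rational ODE
#'
#' Rearranges the fitted implicit relation theta_j = Theta' xi into
#' xdot_k = N_k(x) / D_k(x): terms carrying the derivative variable
#' contribute (with the derivative factor stripped) to the denominator
#' D_k, the remaining terms to the numerator N_k. The rearrangement is
#' exact; no symbolic cancellation beyond constant scaling is
#' attempted.
#'
#' @param model a `candidate_model`.
#' @param deriv_var name of the derivative variable to solve for;
#'   default: the single derivative variable in the candidate lhs.
#' @param state name of the corresponding state; default derived from
#'   the library spec.
#' @return An object of class `rational_ode` with `num` and `den`
#'   (each a list of terms plus coefficients).
#' @export
to_explicit_ode <- function(model, deriv_var = NULL, state = NULL) {
  stopifnot(inherits(model, "candidate_model"))
  spec <- model$spec
  all_derivs <- if (!is.null(spec)) spec$deriv_vars else deriv_var
  if (is.null(deriv_var)) {
    dv <- intersect(names(model$lhs_term$powers), all_derivs)
    if (length(dv) != 1)
      stop("cannot infer the derivative variable; pass deriv_var")
    deriv_var <- dv
  }
  if (is.null(state) && !is.null(spec)) {
    k <- match(deriv_var, spec$derivs)
    state <- if (!is.na(k)) spec$states[k] else deriv_var
  }
  terms <- c(list(model$lhs_term), model$rhs_terms)
  coefs <- c(1, -model$coef)
  num_t <- list(); num_c <- numeric(0)
  den_t <- list(); den_c <- numeric(0)
  for (i in seq_along(terms)) {
    if (coefs[i] == 0) next
    pw <- terms[[i]]$powers
    other <- setdiff(intersect(names(pw), all_derivs), deriv_var)
    if (length(other) > 0)
      stop("not reducible: term '", terms[[i]]$label,
           "' contains another derivative variable")
    dpow <- if (deriv_var %in% names(pw)) pw[[deriv_var]] else 0L
    if (dpow > 1)
      stop("not reducible: derivative appears nonlinearly in term '",
           terms[[i]]$label, "'")
    if (dpow == 1) {
      stripped <- pw[setdiff(names(pw), deriv_var)]
      den_t[[length(den_t) + 1L]] <- new_term(stripped)
      den_c <- c(den_c, coefs[i])
    } else {
      num_t[[length(num_t) + 1L]] <- terms[[i]]
      num_c <- c(num_c, -coefs[i])
    }
  }
  if (length(den_t) == 0)
    stop("not reducible: no term carries the derivative variable")
  structure(list(
    state = state, deriv_var = deriv_var,
    num = list(terms = num_t, coef = num_c,
               labels = vapply(num_t, `[[`, "", "label")),
    den = list(terms = den_t, coef = den_c,
               labels = vapply(den_t, `[[`, "", "label")),
    source_lhs = model$lhs_label, lambda = model$lambda
  ), class = "rational_ode")
}

#' @export
print.rational_ode <- function(x, ...) {
  fmt <- function(side) paste(sprintf("%+.6g*%s", side$coef, side$labels),
                              collapse = " ")
  cat(sprintf("<rational_ode> d%s/dt = N/D\n  N: %s\n  D: %s\n",
              x$state, fmt(x$num), fmt(x$den)))
  invisible(x)
}

#' Normalize a rational ODE by a denominator coefficient
#'
#' Implicit relations are defined only up to scale; for reporting,
#' numerator and denominator are rescaled so that a chosen reference
#' coefficient of D equals 1.
#'
#' @param ode a `rational_ode`.
#' @param by `"constant"` (the constant denominator term), `"max"`
#'   (largest-magnitude denominator coefficient), or a term label.
#' @export
normalize_rational <- function(ode, by = "constant") {
  stopifnot(inherits(ode, "rational_ode"))
  ref <- switch(by,
                constant = match("1", ode$den$labels),
                max = which.max(abs(ode$den$coef)),
                match(by, ode$den$labels))
  if (is.na(ref) || length(ref) == 0)
    stop("reference denominator term not present")
  s <- ode$den$coef[ref]
  if (s == 0) stop("reference denominator coefficient is zero")
  ode$num$coef <- ode$num$coef / s
  ode$den$coef <- ode$den$coef / s
  ode
}

#' Coefficient lookup in a rational ODE
#' @param ode a `rational_ode`.
#' @param label term label.
#' @param side "num" or "den".
#' @export
rational_coef <- function(ode, label, side = c("num", "den")) {
  side <- match.arg(side)
  i <- match(label, ode[[side]]$labels)
  if (is.na(i)) 0 else unname(ode[[side]]$coef[i])
}

# evaluate a list of terms rowwise on a named variable matrix,
# returning the weighted sum (coef %*% terms)
eval_term_sum <- function(terms, coef, vars) {
  if (length(terms) == 0) return(rep(0, nrow(vars)))
  vals <- evaluate_terms(terms, vars)$values
  as.numeric(vals %*% coef)
}

# evaluate N/D at a single named state vector (used inside integrators)
eval_rational_point <- function(ode, vals) {
  vm <- matrix(vals, nrow = 1, dimnames = list(NULL, names(vals)))
  num <- eval_term_sum(ode$num$terms, ode$num$coef, vm)
  den <- eval_term_sum(ode$den$terms, ode$den$coef, vm)
  c(num = num, den = den)
}

#' Simulate a system of identified rational ODEs
#'
#' Integrates xdot_k = N_k(x) / D_k(x) with an adaptive solver. If any
#' denominator magnitude falls below the safeguard `eps_d` the
#' integration terminates early and the partial trajectory is returned
#' with a flag, rather than crashing on the singularity.
#'
#' @param odes list of `rational_ode`, one per state (named by state).
#' @param x0 named initial state.
#' @param times output time grid (increasing).
#' @param control optional function(t) returning a named vector of
#'   control inputs.
#' @param eps_d absolute denominator safeguard; default 1e-8 times the
#'   largest |D_k(x0)|.
#' @param rtol,atol integrator tolerances.
#' @return A `ts_data` (possibly truncated) with attribute
#'   `terminated_early`.
#' @export
simulate_identified <- function(odes, x0, times, control = NULL,
                                eps_d = NULL, rtol = 1e-8, atol = 1e-10) {
  states <- vapply(odes, `[[`, "", "state")
  names(odes) <- states
  if (is.null(names(x0))) names(x0) <- states
  if (!all(states %in% names(x0))) stop("x0 must name every modelled state")
  point_vals <- function(t, y) {
    v <- y
    if (!is.null(control)) v <- c(v, control(t))
    v
  }
  if (is.null(eps_d)) {
    d0 <- vapply(odes, function(o)
      abs(eval_rational_point(o, point_vals(times[1], x0))["den"]), 0)
    eps_d <- 1e-8 * max(d0, 1e-12)
  }
  rhs <- function(t, y, parms) {
    v <- point_vals(t, y)
    nd <- vapply(odes, function(o) eval_rational_point(o, v), numeric(2))
    list(nd["num", ] / nd["den", ])
  }
  rootfun <- function(t, y, parms) {
    v <- point_vals(t, y)
    min(vapply(odes, function(o)
      abs(eval_rational_point(o, v)["den"]), 0)) - eps_d
  }
  sol <- deSolve::lsodar(y = x0[states], times = times, func = rhs,
                         parms = NULL, rootfunc = rootfun,
                         rtol = rtol, atol = atol)
  m <- nrow(sol)
  terminated <- m < length(times)
  X <- sol[, states, drop = FALSE]
  out <- ts_data(sol[, "time"], X)
  attr(out, "terminated_early") <- terminated
  out
}

#' Structure error against a known support
#'
#' Counts library terms incorrectly added to and incorrectly deleted
#' from the identified implicit relation, compared with the true
#' model's support. Comparison is on supports only (implicit relations
#' are defined up to scale), over a shared term vocabulary.
#'
#' @param fit a `candidate_model`, a `sparse_fit` (homogeneous implicit
#'   vector), or a character vector of term labels.
#' @param truth character vector of true support labels.
#' @param vocabulary optional full label vocabulary; if supplied, any
#'   truth label outside it is an error (mismatched vocabularies).
#' @return An object of class `structure_score` with `added`,
#'   `deleted`, `total`, and the offending labels.
#' @export
structure_error <- function(fit, truth, vocabulary = NULL) {
  if (inherits(fit, "candidate_model")) {
    support <- implicit_support(fit)
    if (is.null(vocabulary))
      vocabulary <- c(fit$lhs_label, names(fit$coef))
  } else if (inherits(fit, "sparse_fit")) {
    support <- names(fit$coef)[fit$support]
    if (is.null(vocabulary)) vocabulary <- names(fit$coef)
  } else {
    support <- as.character(fit)
  }
  if (!is.null(vocabulary) && !all(truth %in% vocabulary))
    stop("truth support uses labels outside the model vocabulary: ",
         paste(setdiff(truth, vocabulary), collapse = ", "))
  added <- setdiff(support, truth)
  deleted <- setdiff(truth, support)
  structure(list(added = length(added), deleted = length(deleted),
                 total = length(added) + length(deleted),
                 added_labels = added, deleted_labels = deleted),
            class = "structure_score")
}

#' @export
print.structure_score <- function(x, ...) {
  cat(sprintf("<structure_score> added %d, deleted %d, total %d\n",
              x$added, x$deleted, x$total))
  invisible(x)
}
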