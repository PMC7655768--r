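#' Candidate-function library specification
#'
#' Describes the vocabulary of candidate terms theta_j used to build the
#' regression library Theta(X, Xdot, U). A term is a product of
#' polynomial factors in `poly_vars`, trigonometric factors sin/cos of
#' `trig_vars`, derivative factors in `deriv_vars`, and auxiliary
#' factors in `aux_vars` (used e.g. for spatial-derivative or Laplacian
#' columns in PDE libraries).
#'
#' Derivative factors are capped at multiplicity `deriv_total` per term
#' (default 1): implicit relations affine in each derivative are exactly
#' what allows later conversion to an explicit rational right-hand side.
#' Trigonometric products are capped at total degree `trig_degree`
#' (default 2, enough for products such as sin(phi)cos(phi)); larger
#' caps inflate the library, which is the main practical risk for
#' conditioning and noise robustness.
#'
#' @param states character vector of state-variable names.
#' @param derivs derivative-variable names; default "d" + states.
#' @param controls control-input names (may be empty).
#' @param degree total polynomial degree cap (non-negative integer).
#' @param poly_vars variables entering polynomially; default states and
#'   controls.
#' @param var_caps optional named integer vector of per-variable degree
#'   caps overriding `degree` for specific variables.
#' @param trig_vars subset of `states` entering through sin/cos.
#' @param trig_degree total trig degree cap; default 2.
#' @param deriv_vars derivative variables available as factors; default
#'   `derivs`.
#' @param deriv_total cap on total derivative multiplicity per term.
#' @param aux_vars auxiliary variables (each at most linear).
#' @param aux_total cap on total auxiliary multiplicity per term.
#' @param deriv_poly_cap maximum polynomial degree allowed in terms
#'   that carry a derivative factor (default Inf, i.e. unrestricted).
#'   Setting 0 restricts derivative-bearing terms to trig-only
#'   multipliers, the natural choice for mechanical systems whose
#'   inertia denominators depend on angles alone; it also removes
#'   products of the (noisiest) derivative channel with polynomial
#'   states, which otherwise dominate the library's noise floor.
#' @param deriv_trig_even restrict derivative-bearing terms to trig
#'   multipliers of even total degree (default FALSE). Inertia
#'   matrices of rigid-body systems are quadratic forms in direction
#'   cosines, so cleared Euler-Lagrange denominators carry trig
#'   factors of even degree only; odd-degree rungs such as
#'   cos(phi)*xdd are then pure noise absorbers.
#' @param include_constant include the constant term 1; default TRUE.
#' @return An object of class `library_spec`.
#' @export
library_spec <- function(states, derivs = paste0("d", states),
                         controls = character(), degree = 2,
                         poly_vars = c(states, controls),
                         var_caps = NULL,
                         trig_vars = character(), trig_degree = 2,
                         deriv_vars = derivs, deriv_total = 1,
                         aux_vars = character(), aux_total = 1,
                         deriv_poly_cap = Inf,
                         deriv_trig_even = FALSE,
                         include_constant = TRUE) {
  if (degree < 0) stop("invalid library spec: degree cap must be >= 0")
  if (!all(trig_vars %in% states))
    stop("invalid library spec: trig_vars must be a subset of states")
  spec <- structure(list(
    states = states, derivs = derivs, controls = controls,
    degree = as.integer(degree), poly_vars = poly_vars,
    var_caps = var_caps, trig_vars = trig_vars,
    trig_degree = as.integer(trig_degree),
    deriv_vars = deriv_vars, deriv_total = as.integer(deriv_total),
    aux_vars = aux_vars, aux_total = as.integer(aux_total),
    deriv_poly_cap = deriv_poly_cap,
    deriv_trig_even = isTRUE(deriv_trig_even),
    include_constant = isTRUE(include_constant)
  ), class = "library_spec")
  spec
}

# A single candidate term: named non-negative integer exponents over
# "atoms" (plain variables, or trig atoms like "sin(phi)"), plus its
# printed label. The empty exponent vector is the constant term 1.
new_term <- function(powers) {
  powers <- powers[powers > 0]
  structure(list(powers = powers, label = term_label_from_powers(powers)),
            class = "sindy_term")
}

term_label_from_powers <- function(powers) {
  if (length(powers) == 0) return("1")
  parts <- ifelse(powers == 1, names(powers),
                  paste0(names(powers), "^", powers))
  paste(parts, collapse = "*")
}

#' @export
print.sindy_term <- function(x, ...) {
  cat("<term>", x$label, "\n")
  invisible(x)
}

trig_atoms <- function(trig_vars) {
  if (length(trig_vars) == 0) return(character())
  as.vector(vapply(trig_vars,
                   function(v) c(paste0("sin(", v, ")"), paste0("cos(", v, ")")),
                   character(2)))
}

# Exponent vectors of all monomials over `vars` with total degree
# <= cap and optional per-variable caps. Deterministic recursive order.
enumerate_monomials <- function(vars, cap, var_caps = NULL) {
  if (length(vars) == 0 || cap == 0)
    return(list(stats::setNames(integer(0), character(0))))
  out <- list()
  rec <- function(i, left, acc) {
    if (i > length(vars)) {
      out[[length(out) + 1L]] <<- acc
      return(invisible())
    }
    vcap <- min(left, if (!is.null(var_caps) && vars[i] %in% names(var_caps))
      var_caps[[vars[i]]] else left)
    for (p in 0:vcap) {
      acc2 <- acc
      if (p > 0) acc2[vars[i]] <- p
      rec(i + 1L, left - p, acc2)
    }
  }
  rec(1L, cap, stats::setNames(integer(0), character(0)))
  out
}

#' Enumerate the candidate terms of a library specification
#'
#' Deterministic graded ordering: terms are sorted by total degree
#' (polynomial + trig + derivative + auxiliary exponents), then
#' lexicographically by exponents over the declared atom order. The
#' constant term, when enabled, is therefore always first.
#'
#' @param spec a [library_spec()].
#' @return list of term descriptors (class `sindy_term`).
#' @export
enumerate_terms <- function(spec) {
  stopifnot(inherits(spec, "library_spec"))
  poly <- enumerate_monomials(spec$poly_vars, spec$degree, spec$var_caps)
  # squared sines are capped out: sin^2 v = 1 - cos^2 v would make the
  # trig block algebraically dependent, and an exactly collinear
  # library admits the Pythagorean identity itself as a sparse
  # zero-information "model"
  tatoms <- trig_atoms(spec$trig_vars)
  sin_caps <- stats::setNames(rep(1L, length(spec$trig_vars)),
                              grep("^sin", tatoms, value = TRUE))
  trig <- enumerate_monomials(tatoms, spec$trig_degree, var_caps = sin_caps)
  derv <- enumerate_monomials(spec$deriv_vars, spec$deriv_total)
  aux <- enumerate_monomials(spec$aux_vars, spec$aux_total)
  atom_order <- c(spec$poly_vars, trig_atoms(spec$trig_vars),
                  spec$deriv_vars, spec$aux_vars)
  terms <- list()
  for (d in derv) for (a in aux) for (tg in trig) for (pl in poly) {
    if (length(d) > 0 && sum(pl) > spec$deriv_poly_cap) next
    if (spec$deriv_trig_even && length(d) > 0 && sum(tg) %% 2 == 1) next
    terms[[length(terms) + 1L]] <- new_term(c(pl, tg, d, a))
  }
  labels <- vapply(terms, `[[`, "", "label")
  terms <- terms[!duplicated(labels)]
  if (!spec$include_constant)
    terms <- terms[vapply(terms, function(tm) length(tm$powers) > 0, TRUE)]
  # graded lexicographic sort
  deg <- vapply(terms, function(tm) sum(tm$powers), 0)
  key <- vapply(terms, function(tm) {
    idx <- match(names(tm$powers), atom_order)
    o <- order(idx)
    paste(sprintf("%03d:%03d", idx[o], tm$powers[o]), collapse = "|")
  }, "")
  terms[order(deg, key)]
}

# Evaluate one atom on a variable matrix.
atom_values <- function(atom, vars) {
  m <- regmatches(atom, regexec("^(sin|cos)\\((.+)\\)$", atom))[[1]]
  if (length(m) == 3) {
    v <- m[3]
    if (!v %in% colnames(vars))
      stop(sprintf("variable '%s' referenced by term is not in the data", v))
    return(if (m[2] == "sin") sin(vars[, v]) else cos(vars[, v]))
  }
  if (!atom %in% colnames(vars))
    stop(sprintf("variable '%s' referenced by term is not in the data", atom))
  vars[, atom]
}

#' Evaluate terms on trajectory data
#'
#' Builds the library matrix Theta whose entry (i, j) is term j
#' evaluated at sample i.
#'
#' @param terms list of term descriptors from [enumerate_terms()].
#' @param data a [ts_data()] object, or a named numeric matrix of
#'   variables (one column per variable).
#' @param spec optional [library_spec()] stored for provenance.
#' @return An object of class `library_matrix` with fields `values`
#'   (m x p), `terms`, `labels`, `norms` (NULL until normalized) and
#'   `zero` (flags for exactly-zero columns).
#' @export
evaluate_terms <- function(terms, data, spec = NULL) {
  vars <- if (inherits(data, "ts_data")) ts_variables(data) else as.matrix(data)
  if (is.null(colnames(vars))) stop("variable matrix must have column names")
  m <- nrow(vars)
  p <- length(terms)
  atoms <- unique(unlist(lapply(terms, function(tm) names(tm$powers))))
  cache <- lapply(atoms, atom_values, vars = vars)
  names(cache) <- atoms
  values <- matrix(1, m, p)
  for (j in seq_len(p)) {
    pw <- terms[[j]]$powers
    col <- rep(1, m)
    for (k in seq_along(pw)) col <- col * cache[[names(pw)[k]]]^pw[[k]]
    values[, j] <- col
  }
  labels <- vapply(terms, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("duplicate term labels in library")
  colnames(values) <- labels
  structure(list(values = values, terms = terms, labels = labels,
                 norms = NULL, zero = apply(values == 0, 2, all),
                 spec = spec),
            class = "library_matrix")
}

#' Build a library matrix from data and a specification
#'
#' Convenience wrapper around [enumerate_terms()] and [evaluate_terms()].
#' @inheritParams evaluate_terms
#' @param spec a [library_spec()].
#' @export
build_library <- function(data, spec) {
  evaluate_terms(enumerate_terms(spec), data, spec = spec)
}

#' @export
print.library_matrix <- function(x, ...) {
  cat(sprintf("<library_matrix> %d samples x %d terms%s\n", nrow(x$values),
              length(x$terms), if (!is.null(x$norms)) " (normalized)" else ""))
  cat("  ", paste(utils::head(x$labels, 8), collapse = ", "),
      if (length(x$labels) > 8) ", ...", "\n")
  invisible(x)
}

#' Remove one column as the candidate left-hand side
#'
#' Splits the library into the candidate column theta_j and the reduced
#' library with that column removed, the reformulation that turns the
#' implicit problem into an ordinary regression.
#'
#' @param lib a `library_matrix`.
#' @param j column index (1-based) or a term label.
#' @return list with `lhs` (numeric vector), `lhs_term`, `lhs_label`,
#'   and `reduced` (a `library_matrix` with p - 1 columns in original
#'   order).
#' @export
split_candidate <- function(lib, j) {
  stopifnot(inherits(lib, "library_matrix"))
  if (is.character(j)) j <- match(j, lib$labels)
  if (is.na(j) || j < 1 || j > length(lib$terms))
    stop("candidate index out of range")
  reduced <- lib
  reduced$values <- lib$values[, -j, drop = FALSE]
  reduced$terms <- lib$terms[-j]
  reduced$labels <- lib$labels[-j]
  reduced$zero <- lib$zero[-j]
  reduced$norms <- if (!is.null(lib$norms)) lib$norms[-j]
  list(lhs = lib$values[, j], lhs_term = lib$terms[[j]],
       lhs_label = lib$labels[j], reduced = reduced)
}

#' Normalize library columns to unit Euclidean norm
#'
#' Stores the original norms so fitted coefficients can be mapped back:
#' xi_original = xi_normalized / norm. Exactly-zero columns are flagged,
#' left untouched, and carry norm 0; solvers exclude them.
#'
#' @param lib a `library_matrix`.
#' @export
normalize_columns <- function(lib) {
  stopifnot(inherits(lib, "library_matrix"))
  if (!is.null(lib$norms)) return(lib)
  norms <- sqrt(colSums(lib$values^2))
  zero <- norms == 0
  scl <- ifelse(zero, 1, norms)
  lib$values <- sweep(lib$values, 2, scl, "/")
  lib$norms <- ifelse(zero, 0, norms)
  lib$zero <- zero
  lib
}

# Map coefficients fitted on normalized columns back to the original
# column scaling. Zero-norm columns keep coefficient 0.
denormalize_coefficients <- function(coef, norms) {
  out <- ifelse(norms == 0, 0, coef / ifelse(norms == 0, 1, norms))
  names(out) <- names(coef)
  out
}
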