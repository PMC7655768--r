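#' Sequentially thresholded least squares
#'
#' Alternates a least-squares fit on the active column set with hard
#' thresholding of coefficients whose magnitude falls below `lambda`,
#' until the support is stable or the iteration cap is reached. The
#' returned coefficients are the least-squares fit on the final
#' support; entries off the support are exactly zero.
#'
#' By default both the regressor columns and the target are scaled to
#' unit Euclidean norm before thresholding, so `lambda` is compared
#' against dimensionless coefficients (the relative contribution of a
#' column), and the reported coefficients are mapped back to the
#' original scales. A small ridge term, scaled to the trace of the
#' normal matrix, stabilizes ill-conditioned or underdetermined active
#' sets.
#'
#' @param A regressor matrix (m x p), optionally with column names.
#' @param b target vector (length m).
#' @param lambda hard threshold (> 0) applied to normalized
#'   coefficients.
#' @param max_iter iteration cap (>= 1), default 25.
#' @param ridge ridge stabilizer relative to mean diagonal of the
#'   normal matrix; default 1e-10.
#' @param normalize scale columns of `A` and `b` to unit norm before
#'   thresholding (default TRUE).
#' @return An object of class `sparse_fit`: `coef` (length p, named),
#'   `coef_normalized`, `support` (logical), `residual` and
#'   `relative_residual` (on the original scale), `iterations`,
#'   `converged`, `empty_model`, `lambda`.
#' @export
stlsq <- function(A, b, lambda, max_iter = 25, ridge = 1e-10,
                  normalize = TRUE) {
  A <- as.matrix(A)
  b <- as.numeric(b)
  if (nrow(A) != length(b)) stop("rows of A must match length of b")
  if (ncol(A) < 1) stop("A needs at least one column")
  if (lambda <= 0) stop("lambda must be > 0")
  if (max_iter < 1) stop("max_iter must be >= 1")
  p <- ncol(A)
  labels <- colnames(A)
  if (is.null(labels)) labels <- paste0("c", seq_len(p))
  cn <- sqrt(colSums(A^2))
  bn <- sqrt(sum(b^2))
  if (bn == 0) stop("zero target vector")
  usable <- cn > 0
  if (normalize) {
    An <- sweep(A[, usable, drop = FALSE], 2, cn[usable], "/")
    bnn <- b / bn
  } else {
    An <- A[, usable, drop = FALSE]
    bnn <- b
  }
  k <- ncol(An)
  ls_fit <- function(cols) {
    Asub <- An[, cols, drop = FALSE]
    G <- crossprod(Asub)
    r <- ridge * mean(diag(G))
    solve(G + diag(r, ncol(Asub)), crossprod(Asub, bnn))[, 1]
  }
  active <- seq_len(k)
  w <- ls_fit(active)
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(max_iter)) {
    iters <- it
    keep <- abs(w) >= lambda
    new_active <- active[keep]
    if (length(new_active) == 0) {
      active <- integer(0)
      break
    }
    if (length(new_active) == length(active)) {
      converged <- TRUE
      break
    }
    active <- new_active
    w <- ls_fit(active)
  }
  coef_n <- numeric(p)
  empty <- length(active) == 0
  if (!empty) {
    w <- ls_fit(active)
    # a final threshold pass can in principle still drop entries at the
    # iteration cap; the support reported is exactly the fitted one
    coef_n[which(usable)[active]] <- w
    converged <- converged || all(abs(w) >= lambda)
  } else {
    converged <- TRUE
  }
  coef <- if (normalize) {
    ifelse(cn > 0, coef_n * bn / ifelse(cn > 0, cn, 1), 0)
  } else coef_n
  names(coef) <- labels
  names(coef_n) <- labels
  res <- sqrt(sum((b - A %*% coef)^2))
  structure(list(
    coef = coef, coef_normalized = coef_n, support = coef != 0,
    residual = res, relative_residual = res / bn,
    iterations = iters, converged = converged, empty_model = empty,
    lambda = lambda
  ), class = "sparse_fit")
}

#' @export
print.sparse_fit <- function(x, ...) {
  cat(sprintf("<sparse_fit> %d/%d active terms, lambda = %g, rel. residual = %.3g%s\n",
              sum(x$support), length(x$coef), x$lambda, x$relative_residual,
              if (isTRUE(x$empty_model)) " (empty model)" else ""))
  if (sum(x$support) > 0) {
    cf <- x$coef[x$support]
    for (i in seq_along(cf))
      cat(sprintf("  %-24s %+.6g\n", names(cf)[i], cf[i]))
  }
  invisible(x)
}

#' Constrained joint sparse solve with zero diagonal
#'
#' Reconstructs every library column from the remaining columns in one
#' pass, under the constraint diag(Xi) = 0 that removes the trivial
#' identity solution. The constrained problem decouples: fixing the
#' diagonal of column j to zero is exactly equivalent to deleting
#' column j from the regressor set and solving an ordinary sparse
#' regression for it, so the implementation runs p independent
#' thresholded least-squares fits and reassembles the p x p matrix.
#'
#' @param lib a `library_matrix`.
#' @param lambda threshold passed to [stlsq()] (scalar, or length-p
#'   vector giving a per-column lambda_j).
#' @param ... further arguments passed to [stlsq()].
#' @return p x p coefficient matrix Xi with exact zeros on the
#'   diagonal; column j holds the sparse reconstruction of library
#'   column j.
#' @export
constrained_joint_solve <- function(lib, lambda = 0.1, ...) {
  stopifnot(inherits(lib, "library_matrix"))
  p <- length(lib$terms)
  if (p < 2) stop("constrained joint solve needs at least 2 columns")
  lambda <- rep_len(lambda, p)
  Xi <- matrix(0, p, p, dimnames = list(lib$labels, lib$labels))
  for (j in seq_len(p)) {
    if (lib$zero[j]) next
    sp <- split_candidate(lib, j)
    fit <- stlsq(sp$reduced$values, sp$lhs, lambda[j], ...)
    Xi[-j, j] <- fit$coef
  }
  Xi
}

# soft-thresholding operator
soft_threshold <- function(x, s) sign(x) * pmax(abs(x) - s, 0)

#' Dimension of the numerical null space of a library
#'
#' Counts singular values below `cutoff` times the largest singular
#' value, after scaling columns to unit norm.
#'
#' @param lib a `library_matrix`.
#' @param cutoff relative singular-value cutoff (default 1e-8).
#' @export
nullspace_dimension <- function(lib, cutoff = 1e-8) {
  nl <- normalize_columns(lib)
  vals <- nl$values[, !nl$zero, drop = FALSE]
  d <- svd(vals, nu = 0, nv = 0)$d
  sum(d < cutoff * d[1])
}

#' Implicit-SINDy baseline: sparsest null-space vector via ADM
#'
#' The null-space route to implicit identification: compute an SVD
#' basis of the numerical null space of the (column-normalized)
#' library, then search it for the sparsest unit vector with the
#' alternating directions method, restarted from several seeded
#' initializations. Small entries are pruned and the vector is refined
#' as the smallest right singular vector of the library restricted to
#' the pruned support.
#'
#' This route degrades sharply with noise: measurement noise perturbs
#' the small singular values, and once no singular value falls below
#' the cutoff there is no numerical null space left to search (the
#' "no null space" error), while looser cutoffs admit spurious
#' directions that derail the search.
#'
#' @param lib a `library_matrix`.
#' @param cutoff relative singular-value cutoff defining the null
#'   space (default 1e-8).
#' @param adm_lambda soft-threshold used inside ADM (default 1e-2).
#' @param restarts number of seeded initializations (default 10).
#' @param prune relative magnitude below which entries are pruned from
#'   the support (default 1e-2).
#' @param seed integer seed for the random restarts.
#' @param max_iter,tol ADM iteration controls.
#' @return A `sparse_fit` whose `coef` is the unit-norm implicit
#'   coefficient vector on the original column scaling, with positive
#'   first nonzero entry; `nullspace_dim` records the dimension used.
#' @export
adm_implicit_sindy <- function(lib, cutoff = 1e-8, adm_lambda = 1e-2,
                               restarts = 10, prune = 1e-2, seed = 1,
                               max_iter = 200, tol = 1e-8) {
  stopifnot(inherits(lib, "library_matrix"))
  p <- length(lib$terms)
  if (p < 2) stop("implicit identification needs at least 2 columns")
  nl <- normalize_columns(lib)
  usable <- !nl$zero
  vals <- nl$values[, usable, drop = FALSE]
  sv <- svd(vals)
  keep <- sv$d < cutoff * sv$d[1]
  r <- sum(keep)
  if (r == 0)
    stop("no null space: no singular value below the cutoff (noise has closed the null space)")
  N <- sv$v[, keep, drop = FALSE]
  adm_run <- function(q) {
    for (it in seq_len(max_iter)) {
      y <- soft_threshold(N %*% q, adm_lambda)
      if (all(y == 0)) break
      q_new <- crossprod(N, y)
      q_new <- q_new / sqrt(sum(q_new^2))
      if (sqrt(sum((q_new - q)^2)) < tol) {
        q <- q_new
        break
      }
      q <- q_new
    }
    q
  }
  k <- ncol(vals)
  best <- NULL
  inits <- vector("list", 0)
  for (i in seq_len(min(r, restarts))) inits[[length(inits) + 1L]] <- diag(r)[, i]
  n_rand <- max(0, restarts - length(inits))
  if (n_rand > 0) {
    rand <- with_seed(seed, matrix(stats::rnorm(r * n_rand), r))
    for (i in seq_len(n_rand)) {
      q <- rand[, i]
      inits[[length(inits) + 1L]] <- q / sqrt(sum(q^2))
    }
  }
  for (q0 in inits) {
    xi <- as.numeric(N %*% adm_run(q0))
    if (all(xi == 0)) next
    supp <- abs(xi) >= prune * max(abs(xi))
    if (sum(supp) == 0) next
    # refine on the pruned support: smallest right singular vector of
    # the restricted library; iterate pruning until the support is
    # self-consistent (refinement can reveal further negligible entries)
    resid <- NA_real_
    v <- NULL
    for (pass in 1:5) {
      sub <- svd(vals[, supp, drop = FALSE])
      v <- sub$v[, ncol(sub$v)]
      resid <- sub$d[length(sub$d)] / sv$d[1]
      keep <- abs(v) >= prune * max(abs(v))
      if (all(keep)) break
      supp[supp] <- keep
      v <- v[keep]
      if (sum(supp) == 0) break
    }
    if (sum(supp) == 0) next
    xi_ref <- numeric(k)
    xi_ref[supp] <- v
    cand <- list(xi = xi_ref, support = supp, residual = resid)
    if (is.null(best) || sum(supp) < sum(best$support) ||
        (sum(supp) == sum(best$support) && resid < best$residual))
      best <- cand
  }
  if (is.null(best)) stop("ADM failed to find a nonzero sparse null vector")
  # back to the original column scaling; unit norm; positive leading entry
  coef <- numeric(p)
  coef[usable] <- best$xi / ifelse(nl$norms[usable] > 0, nl$norms[usable], 1)
  coef <- coef / sqrt(sum(coef^2))
  first <- which(coef != 0)[1]
  if (coef[first] < 0) coef <- -coef
  names(coef) <- lib$labels
  structure(list(
    coef = coef, coef_normalized = NULL, support = coef != 0,
    residual = best$residual, relative_residual = best$residual,
    iterations = NA_integer_, converged = TRUE, empty_model = FALSE,
    lambda = adm_lambda, nullspace_dim = r
  ), class = "sparse_fit")
}

# evaluate code with a temporary RNG state seeded by `seed`
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
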