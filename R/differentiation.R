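#' Second-order central differences
#'
#' Centered stencil in the interior, one-sided second-order stencils at
#' the two boundaries, so the output has the same length as the input.
#'
#' @param x numeric vector or matrix (columns differentiated
#'   independently) sampled on a uniform grid.
#' @param dt sampling step (> 0).
#' @return derivative of the same shape as `x`.
#' @export
central_difference <- function(x, dt) {
  if (is.matrix(x)) return(apply(x, 2, central_difference, dt = dt))
  n <- length(x)
  if (n < 3) stop("central_difference needs at least 3 samples")
  if (dt <= 0) stop("dt must be > 0")
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d[1] <- (-3 * x[1] + 4 * x[2] - x[3]) / (2 * dt)
  d[n] <- (3 * x[n] - 4 * x[n - 1] + x[n - 2]) / (2 * dt)
  d
}

#' Differentiation configuration
#'
#' @param scheme "central" or "tvreg".
#' @param dt sampling step (s).
#' @param alpha total-variation regularization weight (> 0, tvreg only).
#' @param iterations outer lagged-diffusivity iterations (tvreg only).
#' @export
diff_config <- function(scheme = c("central", "tvreg"), dt, alpha = 1e-2,
                        iterations = 10) {
  scheme <- match.arg(scheme)
  if (dt <= 0) stop("dt must be > 0")
  if (scheme == "tvreg" && (alpha <= 0 || iterations < 1))
    stop("tvreg requires alpha > 0 and iterations >= 1")
  structure(list(scheme = scheme, dt = dt, alpha = alpha,
                 iterations = iterations), class = "diff_config")
}

#' @rdname diff_config
#' @param series numeric vector or matrix to differentiate.
#' @param config a `diff_config`.
#' @export
differentiate <- function(series, config) {
  stopifnot(inherits(config, "diff_config"))
  if (config$scheme == "central") central_difference(series, config$dt)
  else tvreg_diff(series, config$dt, alpha = config$alpha,
                  iterations = config$iterations)
}

# integration operator A (cumulative trapezoid, (Au)[1] = 0) and its
# transpose, applied matrix-free.
tv_A <- function(u, dt) dt * (cumsum(u) - 0.5 * (u + u[1]))
tv_At <- function(v, dt) {
  n <- length(v)
  s <- rev(cumsum(rev(v)))               # s[j] = sum_{i >= j} v_i
  out <- dt * (s - 0.5 * v)
  out[1] <- dt * 0.5 * (s[1] - v[1])
  out
}

#' Total-variation regularized differentiation
#'
#' Estimates the derivative u of a noisy uniformly sampled signal f by
#' minimizing alpha * sum(|Du|) + 0.5 * ||Au - (f - f1)||^2, where A is
#' cumulative trapezoidal integration and D a forward difference. The
#' total-variation penalty favours derivatives that are piecewise
#' smooth, suppressing the noise amplification of finite differences.
#' Solved by lagged-diffusivity fixed-point iteration; each linear
#' subproblem is solved matrix-free by conjugate gradients, so long
#' records are handled without forming dense operators.
#'
#' @param x noisy signal, numeric vector or matrix (columns treated
#'   independently).
#' @param dt sampling step (s).
#' @param alpha regularization weight (> 0). Larger values give flatter
#'   (lower total-variation) derivative estimates.
#' @param iterations outer fixed-point iterations (default 10).
#' @param eps smoothing of |.| in the TV weight (default 1e-8).
#' @param tol relative-change convergence tolerance for the outer loop.
#' @param cg_tol,cg_maxit conjugate-gradient stopping controls.
#' @return derivative estimate with attributes `converged` (logical) and
#'   `iterations` (outer iterations used). Non-convergence returns the
#'   best iterate with `converged = FALSE` and a warning.
#' @export
tvreg_diff <- function(x, dt, alpha = 1e-2, iterations = 10, eps = 1e-8,
                       tol = 1e-6, cg_tol = 1e-10, cg_maxit = 300) {
  if (is.matrix(x)) {
    out <- apply(x, 2, tvreg_diff, dt = dt, alpha = alpha,
                 iterations = iterations, eps = eps, tol = tol,
                 cg_tol = cg_tol, cg_maxit = cg_maxit)
    return(out)
  }
  if (alpha <= 0) stop("alpha must be > 0")
  if (iterations < 1) stop("iterations must be >= 1")
  n <- length(x)
  if (n < 3) stop("tvreg_diff needs at least 3 samples")
  fhat <- x - x[1]
  rhs <- tv_At(fhat, dt)
  u <- central_difference(x, dt)
  converged <- FALSE
  used <- iterations
  for (it in seq_len(iterations)) {
    du <- diff(u) / dt
    w <- 1 / sqrt(du^2 + eps^2)
    # H v = alpha * dt * D' diag(w) D v + A'A v
    Hv <- function(v) {
      dv <- diff(v) / dt
      wd <- w * dv
      tv <- (c(0, wd) - c(wd, 0)) / dt
      alpha * dt * tv + tv_At(tv_A(v, dt), dt)
    }
    u_new <- cg_solve(Hv, rhs, x0 = u, tol = cg_tol, maxit = cg_maxit)
    delta <- sqrt(sum((u_new - u)^2)) / max(sqrt(sum(u^2)), .Machine$double.eps)
    u <- u_new
    if (delta < tol) {
      converged <- TRUE
      used <- it
      break
    }
  }
  if (!converged) warning("tvreg_diff: outer iteration did not converge; returning best iterate")
  attr(u, "converged") <- converged
  attr(u, "iterations") <- used
  u
}

# plain conjugate gradients for SPD operator given as a function
cg_solve <- function(Hv, b, x0 = NULL, tol = 1e-10, maxit = 300) {
  x <- if (is.null(x0)) numeric(length(b)) else x0
  r <- b - Hv(x)
  p <- r
  rs <- sum(r^2)
  b2 <- max(sum(b^2), .Machine$double.eps)
  for (i in seq_len(maxit)) {
    if (rs / b2 < tol^2) break
    Hp <- Hv(p)
    a <- rs / sum(p * Hp)
    x <- x + a * p
    r <- r - a * Hp
    rs_new <- sum(r^2)
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  x
}

# discrete total variation of a signal (sum of absolute increments)
total_variation <- function(u) sum(abs(diff(u)))
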