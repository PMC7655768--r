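#' Space-time field container
#'
#' A scalar field sampled on a uniform (x, t) grid, with an optional
#' stored time-derivative field.
#'
#' @param x spatial grid (uniform).
#' @param t time grid (uniform).
#' @param u nx x nt matrix of field values (space down the rows).
#' @param ut optional nx x nt matrix of time derivatives.
#' @param periodic is the spatial domain periodic?
#' @export
field_data <- function(x, t, u, ut = NULL, periodic = TRUE) {
  u <- as.matrix(u)
  if (nrow(u) != length(x) || ncol(u) != length(t))
    stop("u must be length(x) x length(t)")
  if (!is.null(ut) && !all(dim(ut) == dim(u)))
    stop("ut must have the same shape as u")
  structure(list(x = x, t = t, u = u, ut = ut,
                 dx = x[2] - x[1], dt = t[2] - t[1],
                 periodic = periodic), class = "field_data")
}

#' @export
print.field_data <- function(x, ...) {
  cat(sprintf("<field_data> %d x %d (space x time), dx = %g, dt = %g%s\n",
              nrow(x$u), ncol(x$u), x$dx, x$dt,
              if (x$periodic) ", periodic" else ""))
  invisible(x)
}

# wavenumbers for a periodic domain of length L discretized with n points
spectral_k <- function(n, L) {
  (2 * pi / L) * c(0:(n / 2), (-n / 2 + 1):(-1))
}

spectral_deriv_vec <- function(u, k, order) {
  mult <- (1i * k)^order
  if (order %% 2 == 1) mult[length(k) %/% 2 + 1] <- 0  # Nyquist mode
  Re(stats::fft(stats::fft(u) * mult, inverse = TRUE)) / length(u)
}

# periodic circular shift (positive s shifts indices forward)
pshift <- function(u, s) {
  n <- length(u)
  u[((seq_len(n) - 1 + s) %% n) + 1]
}

fd_deriv_vec <- function(u, dx, order) {
  if (order == 1) {
    (-pshift(u, 2) + 8 * pshift(u, 1) - 8 * pshift(u, -1) + pshift(u, -2)) /
      (12 * dx)
  } else if (order == 2) {
    (-pshift(u, 2) + 16 * pshift(u, 1) - 30 * u + 16 * pshift(u, -1) -
       pshift(u, -2)) / (12 * dx^2)
  } else if (order == 3) {
    (pshift(u, 3) - 8 * pshift(u, 2) + 13 * pshift(u, 1) -
       13 * pshift(u, -1) + 8 * pshift(u, -2) - pshift(u, -3)) / (8 * dx^3)
  } else stop("finite-difference scheme implements orders 1-3")
}

#' Spatial derivatives of a field
#'
#' Spectral (Fourier) or fourth-order central finite-difference
#' derivatives along the spatial axis, column by column. Spectral
#' differentiation requires a periodic domain and is exact for
#' band-limited fields.
#'
#' @param field a `field_data`, or a numeric matrix/vector (then `dx`
#'   must be given).
#' @param order derivative order (>= 1).
#' @param scheme "spectral" or "fd".
#' @param dx grid spacing (taken from the `field_data` if omitted).
#' @param max_order configured cap on the derivative order (default 4).
#' @return array of derivatives with the same shape as the input.
#' @export
spatial_derivatives <- function(field, order = 1,
                                scheme = c("spectral", "fd"),
                                dx = NULL, max_order = 4) {
  scheme <- match.arg(scheme)
  if (order < 1 || order > max_order)
    stop(sprintf("derivative order %d exceeds the configured maximum %d",
                 order, max_order))
  if (inherits(field, "field_data")) {
    if (scheme == "spectral" && !field$periodic)
      stop("spectral derivatives require a periodic domain")
    u <- field$u
    dx <- field$dx
  } else {
    u <- field
    if (is.null(dx)) stop("dx required for plain matrix input")
  }
  vec <- is.null(dim(u))
  u <- as.matrix(u)
  n <- nrow(u)
  out <- if (scheme == "spectral") {
    k <- spectral_k(n, n * dx)
    apply(u, 2, spectral_deriv_vec, k = k, order = order)
  } else {
    apply(u, 2, fd_deriv_vec, dx = dx, order = order)
  }
  if (vec) as.numeric(out) else out
}

#' Modified Korteweg-de Vries equation with loss and gain
#'
#' u_t = -u_xxx - 6 u u_x - gamma u + 2 g0 / (1 + u) on a periodic
#' domain: the classical KdV advection-dispersion balance, a linear
#' loss term, and a rational gain term that saturates as u grows. The
#' gain makes the PDE implicit: cleared of its denominator the
#' dynamics couples u_t with u_t * u.
#'
#' @param gamma loss coefficient (default 0.1).
#' @param g0 gain coefficient (default 1).
#' @param L domain length (domain is [-L/2, L/2), default 40).
#' @param n number of grid points (power of two, >= 64; default 128).
#' @param dt internal time step of the exponential integrator.
#' @export
kdv_params <- function(gamma = 0.1, g0 = 1, L = 40, n = 128, dt = 1e-3) {
  if (n < 64 || bitwAnd(n, n - 1L) != 0)
    stop("n must be a power of two >= 64")
  list(gamma = gamma, g0 = g0, L = L, n = as.integer(n), dt = dt)
}

kdv_rhs_field <- function(u, k, gamma, g0) {
  uh <- stats::fft(u)
  ux <- spectral_deriv_vec(u, k, 1)
  uxxx <- spectral_deriv_vec(u, k, 3)
  -uxxx - 6 * u * ux - gamma * u + 2 * g0 / (1 + u)
}

# ETDRK4 coefficients by the contour-integral trick (stable for the
# nearly defective modes near k = 0)
etdrk4_coefs <- function(Lhat, dt, M = 32) {
  E <- exp(dt * Lhat)
  E2 <- exp(dt * Lhat / 2)
  r <- exp(1i * pi * ((1:M) - 0.5) / M)
  LR <- outer(dt * Lhat, r, "+")
  Q <- dt * rowMeans((exp(LR / 2) - 1) / LR)
  f1 <- dt * rowMeans((-4 - LR + exp(LR) * (4 - 3 * LR + LR^2)) / LR^3)
  f2 <- dt * rowMeans((2 + LR + exp(LR) * (-2 + LR)) / LR^3)
  f3 <- dt * rowMeans((-4 - 3 * LR - LR^2 + exp(LR) * (4 - LR)) / LR^3)
  list(E = E, E2 = E2, Q = Q, f1 = f1, f2 = f2, f3 = f3)
}

#' @rdname kdv_params
#' @param params parameter list from [kdv_params()].
#' @param u0 initial profile: a function of x or a numeric vector;
#'   default two well-separated positive humps.
#' @param T time horizon.
#' @param dt_out output sampling step (default 0.01).
#' @return A [field_data()] with the analytic u_t stored at every
#'   snapshot; attribute `aborted` flags an early stop if 1 + u
#'   touched zero.
#' @export
simulate_modified_kdv <- function(params = kdv_params(), u0 = NULL,
                                  T = 10, dt_out = 0.01) {
  n <- params$n
  x <- -params$L / 2 + params$L * (0:(n - 1)) / n
  if (is.null(u0))
    u0 <- function(x) 0.8 * exp(-((x + 6) / 3)^2) + 0.4 * exp(-((x - 2) / 3)^2)
  u <- if (is.function(u0)) u0(x) else as.numeric(u0)
  if (length(u) != n) stop("u0 must have length n")
  if (min(1 + u) <= 0) stop("initial condition violates 1 + u > 0")
  k <- spectral_k(n, params$L)
  # linear part i k^3 - gamma (dispersion + loss), nonlinear part
  # -3 d/dx(u^2) + gain, advanced by ETDRK4
  Lhat <- 1i * k^3 - params$gamma
  cf <- etdrk4_coefs(Lhat, params$dt)
  gmul <- 1i * k
  gmul[n %/% 2 + 1] <- 0
  Nl <- function(vh) {
    u <- Re(stats::fft(vh, inverse = TRUE)) / n
    -3 * gmul * stats::fft(u * u) + stats::fft(2 * params$g0 / (1 + u))
  }
  every <- max(1L, round(dt_out / params$dt))
  nsteps <- round(T / params$dt)
  nsave <- nsteps %/% every + 1L
  usave <- matrix(NA_real_, n, nsave)
  tsave <- numeric(nsave)
  usave[, 1] <- u
  vh <- stats::fft(u)
  aborted <- FALSE
  isave <- 1L
  for (step in seq_len(nsteps)) {
    Nv <- Nl(vh)
    a <- cf$E2 * vh + cf$Q * Nv
    Na <- Nl(a)
    b <- cf$E2 * vh + cf$Q * Na
    Nb <- Nl(b)
    c2 <- cf$E2 * a + cf$Q * (2 * Nb - Nv)
    Nc <- Nl(c2)
    vh <- cf$E * vh + cf$f1 * Nv + 2 * cf$f2 * (Na + Nb) + cf$f3 * Nc
    if (step %% every == 0) {
      u <- Re(stats::fft(vh, inverse = TRUE)) / n
      if (min(1 + u) <= 1e-6) {
        aborted <- TRUE
        break
      }
      isave <- isave + 1L
      usave[, isave] <- u
      tsave[isave] <- step * params$dt
    }
  }
  usave <- usave[, seq_len(isave), drop = FALSE]
  tsave <- tsave[seq_len(isave)]
  ut <- apply(usave, 2, kdv_rhs_field, k = k, gamma = params$gamma,
              g0 = params$g0)
  out <- field_data(x, tsave, usave, ut = ut, periodic = TRUE)
  attr(out, "aborted") <- aborted
  out
}

#' Implicit / explicit PDE library for the modified KdV equation
#'
#' Polynomials in u up to degree 2, one spatial-derivative factor
#' (u_x, u_xx or u_xxx) and, in the implicit variant, one u_t factor
#' per term: 24 terms, containing the denominator-cleared form
#' u_t (1 + u) = -(1 + u)(u_xxx + 6 u u_x + gamma u) + 2 g0.
#'
#' @param explicit drop all u_t-bearing terms (the vocabulary of the
#'   explicit regression baseline); default FALSE.
#' @export
kdv_library_spec <- function(explicit = FALSE) {
  library_spec(states = "u", derivs = "u_t", degree = 2,
               deriv_vars = if (explicit) character() else "u_t",
               aux_vars = c("u_x", "u_xx", "u_xxx"), aux_total = 1)
}

#' @rdname kdv_library_spec
#' @param field a `field_data` from [simulate_modified_kdv()].
#' @return named list of nx x nt variable fields (u, u_x, u_xx,
#'   u_xxx, u_t) for PDE library building.
#' @export
kdv_variables <- function(field) {
  list(u = field$u,
       u_x = spatial_derivatives(field, 1),
       u_xx = spatial_derivatives(field, 2),
       u_xxx = spatial_derivatives(field, 3),
       u_t = field$ut)
}

#' @rdname kdv_library_spec
#' @param g0 gain coefficient of the data-generating run.
#' @return true implicit support (labels) of the cleared-denominator
#'   relation; with g0 = 0 the dynamics is explicit and the minimal
#'   relation has four terms.
#' @export
kdv_truth_support <- function(g0 = 1) {
  if (g0 == 0) return(c("u", "u*u_x", "u_xxx", "u_t"))
  c("1", "u", "u^2", "u*u_x", "u^2*u_x", "u_xxx", "u*u_xxx",
    "u_t", "u*u_t")
}

#' Simplified Belousov-Zhabotinsky reaction-diffusion model
#'
#' Four coupled fields (x, z, s, u) with Oregonator-style kinetics on
#' a periodic 1-D domain; the activator equation carries the rational
#' term f z (q - x)/(q + x) that makes the system implicit. Kinetic
#' parameters are exposed configuration with documented defaults
#' chosen to give smooth, strictly positive dynamics on the default
#' horizon.
#'
#' @param eps,eps2,eps3 timescale separations (> 0).
#' @param f stoichiometric factor.
#' @param q excitability parameter (> 0).
#' @param alpha,beta,gamma,chi,chi2 kinetic constants.
#' @param Dx,Dz,Ds,Du diffusion coefficients (relative to u's).
#'   Defaults put the system in an excitable regime whose fields
#'   traverse a wide dynamic range within the default horizon, with an
#'   activator diffusion strong enough that both Laplacian terms of
#'   the cleared activator equation carry identifiable weight.
#' @export
bz_params <- function(eps = 0.1, eps2 = 0.1, eps3 = 0.3, f = 1.2,
                      q = 0.02, alpha = 0.3, beta = 0.26, gamma = 0.4,
                      chi = 0.1, chi2 = 0.1,
                      Dx = 3, Dz = 1, Ds = 1, Du = 1) {
  if (min(eps, eps2, eps3) <= 0) stop("eps, eps2, eps3 must be > 0")
  if (q <= 0) stop("q must be > 0")
  list(eps = eps, eps2 = eps2, eps3 = eps3, f = f, q = q, alpha = alpha,
       beta = beta, gamma = gamma, chi = chi, chi2 = chi2,
       Dx = Dx, Dz = Dz, Ds = Ds, Du = Du)
}

bz_reaction <- function(st, p) {
  x <- st$x; z <- st$z; s <- st$s; u <- st$u
  list(x = (p$f * z * (p$q - x) / (p$q + x) + x - x^2 - p$beta * x + s) / p$eps,
       z = x - z - p$alpha * z + p$gamma * u,
       s = (p$beta * x - s + p$chi * u) / p$eps2,
       u = (p$alpha * z - (p$gamma + p$chi2) * u) / p$eps3)
}

#' @rdname bz_params
#' @param params parameter list from [bz_params()].
#' @param init optional named list of initial fields (x, z, s, u) as
#'   functions of the grid or numeric vectors; default: positive
#'   mixtures of Gaussians.
#' @param T time horizon (default 1).
#' @param dt time step (default 0.001).
#' @param n grid points (default 128).
#' @param xlim spatial domain (default c(-10, 10)).
#' @param dt_out output sampling step; defaults to every integration
#'   step so that the fast off-attractor transients, which carry most
#'   of the identification signal for the slaved fields, are retained.
#' @return list of class `bz_fields`: grid `x`, times `t`, `fields`
#'   and analytic time-derivative `dfields` (each a named list of
#'   nx x nt matrices). Attribute `aborted` flags q + x reaching 0.
#' @export
simulate_bz <- function(params = bz_params(), init = NULL, T = 1,
                        dt = 1e-3, n = 128, xlim = c(-10, 10),
                        dt_out = dt) {
  Ldom <- diff(xlim)
  y <- xlim[1] + Ldom * (0:(n - 1)) / n
  if (is.null(init)) {
    init <- list(
      x = function(y) 0.4 + 0.3 * exp(-((y + 4) / 1.5)^2) + 0.2 * exp(-((y - 2) / 2)^2),
      z = function(y) 0.3 + 0.2 * exp(-((y - 4) / 2)^2) + 0.1 * exp(-((y + 1) / 1.5)^2),
      s = function(y) 0.2 + 0.1 * exp(-(y / 2)^2),
      u = function(y) 0.25 + 0.15 * exp(-((y - 1) / 2)^2))
  }
  st <- lapply(init, function(f0) if (is.function(f0)) f0(y) else as.numeric(f0))
  stopifnot(all(c("x", "z", "s", "u") %in% names(st)))
  k <- spectral_k(n, Ldom)
  Dcoef <- c(x = params$Dx, z = params$Dz, s = params$Ds, u = params$Du)
  diff_mult <- lapply(Dcoef, function(D) exp(-k^2 * D * dt))
  lap <- function(v) spectral_deriv_vec(v, k, 2)
  full_rhs <- function(st) {
    r <- bz_reaction(st, params)
    lapply(stats::setNames(names(r), names(r)),
           function(nm) r[[nm]] + Dcoef[[nm]] * lap(st[[nm]]))
  }
  every <- max(1L, round(dt_out / dt))
  nsteps <- round(T / dt)
  nsave <- nsteps %/% every + 1L
  fields <- lapply(st, function(v) {
    m <- matrix(NA_real_, n, nsave)
    m[, 1] <- v
    m
  })
  tsave <- numeric(nsave)
  aborted <- FALSE
  isave <- 1L
  rk4_reaction <- function(st) {
    k1 <- bz_reaction(st, params)
    st2 <- Map(function(v, d) v + dt / 2 * d, st, k1)
    k2 <- bz_reaction(st2, params)
    st3 <- Map(function(v, d) v + dt / 2 * d, st, k2)
    k3 <- bz_reaction(st3, params)
    st4 <- Map(function(v, d) v + dt * d, st, k3)
    k4 <- bz_reaction(st4, params)
    Map(function(v, a, b, c2, d) v + dt / 6 * (a + 2 * b + 2 * c2 + d),
        st, k1, k2, k3, k4)
  }
  for (step in seq_len(nsteps)) {
    st <- rk4_reaction(st)
    st <- lapply(stats::setNames(names(st), names(st)), function(nm)
      Re(stats::fft(stats::fft(st[[nm]]) * diff_mult[[nm]], inverse = TRUE)) / n)
    if (min(params$q + st$x) <= 0) {
      aborted <- TRUE
      break
    }
    if (step %% every == 0) {
      isave <- isave + 1L
      for (nm in names(st)) fields[[nm]][, isave] <- st[[nm]]
      tsave[isave] <- step * dt
    }
  }
  fields <- lapply(fields, function(m) m[, seq_len(isave), drop = FALSE])
  tsave <- tsave[seq_len(isave)]
  dfields <- vector("list", length(fields))
  names(dfields) <- paste0(names(fields), "_t")
  for (j in seq_len(isave)) {
    stj <- lapply(fields, function(m) m[, j])
    rj <- full_rhs(stj)
    for (nm in names(rj)) dfields[[paste0(nm, "_t")]][[j]] <- rj[[nm]]
  }
  dfields <- lapply(dfields, function(cols) do.call(cbind, cols))
  out <- structure(list(x = y, t = tsave, fields = fields,
                        dfields = dfields, dx = y[2] - y[1],
                        params = params), class = "bz_fields")
  attr(out, "aborted") <- aborted
  out
}

#' Implicit library for the BZ activator equation
#'
#' Cubic monomials in the species that enter the activator kinetics
#' (x, z, s), optionally multiplied by the activator Laplacian column
#' and/or the activator time derivative: 80 terms, containing the
#' (q + x)-cleared form of the activator equation. Restricting the
#' polynomial vocabulary to the chemically coupled species is the same
#' kind of expert trimming as restricting trigonometric terms to
#' rotation angles in the mechanical examples; it is what keeps the
#' cubic library conditioned well enough for sparse regression.
#' @export
bz_x_library_spec <- function() {
  library_spec(states = c("x", "z", "s", "u"), derivs = "x_t",
               degree = 3, poly_vars = c("x", "z", "s"),
               deriv_vars = "x_t", aux_vars = "lap_x")
}

#' @rdname bz_x_library_spec
#' @param bz a `bz_fields` object from [simulate_bz()].
#' @return named list of variable fields for the activator library.
#' @export
bz_x_variables <- function(bz) {
  list(x = bz$fields$x, z = bz$fields$z, s = bz$fields$s,
       u = bz$fields$u,
       lap_x = spatial_derivatives(bz$fields$x, 2, dx = bz$dx),
       x_t = bz$dfields$x_t)
}

#' @rdname bz_x_library_spec
#' @export
bz_x_truth_support <- function() {
  c("x", "x^2", "x^3", "z", "x*z", "s", "x*s", "x_t", "x*x_t",
    "lap_x", "x*lap_x")
}
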