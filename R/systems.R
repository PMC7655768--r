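# Synthetic benchmark systems. Every simulator integrates with tight
# adaptive tolerances and returns a ts_data whose derivative block is
# evaluated analytically from the right-hand side (not numerically
# differentiated), so differentiation noise is opt-in.

sim_with_derivs <- function(rhs, x0, times, state_names, params,
                            control = NULL, control_names = NULL,
                            rtol = 1e-8, atol = 1e-10, method = "lsoda") {
  y0 <- stats::setNames(as.numeric(x0), state_names)
  f <- function(t, y, p) list(rhs(t, y, p))
  sol <- deSolve::ode(y = y0, times = times, func = f, parms = params,
                      rtol = rtol, atol = atol, method = method)
  X <- unname(sol[, state_names, drop = FALSE])
  colnames(X) <- state_names
  vals <- vapply(seq_len(nrow(sol)),
                 function(i) as.numeric(rhs(sol[i, "time"], X[i, ], params)),
                 numeric(length(state_names)))
  Xdot <- if (length(state_names) == 1) matrix(vals, ncol = 1) else t(vals)
  colnames(Xdot) <- paste0("d", state_names)
  U <- NULL
  if (!is.null(control)) {
    U <- matrix(vapply(sol[, "time"], function(t) control(t), numeric(length(control_names))),
                ncol = length(control_names), byrow = TRUE)
    colnames(U) <- control_names
  }
  ts_data(sol[, "time"], X, Xdot = Xdot, U = U)
}

#' Michaelis-Menten enzyme kinetics
#'
#' One-dimensional substrate model xdot = jx - Vmax * x / (Km + x):
#' constant substrate influx jx balanced against saturating enzymatic
#' uptake with maximum rate Vmax and half-maximal concentration Km.
#' The rational uptake term makes this the canonical small test case
#' for implicit identification.
#'
#' @param jx substrate influx (default 0.6).
#' @param Vmax maximum reaction rate (default 1.5).
#' @param Km half-maximal concentration (default 0.3, must be > 0).
#' @export
mm_params <- function(jx = 0.6, Vmax = 1.5, Km = 0.3) {
  if (Km <= 0 || Vmax < 0) stop("Km must be > 0 and Vmax >= 0")
  list(jx = jx, Vmax = Vmax, Km = Km)
}

mm_rhs <- function(t, y, p) {
  if (y[1] + p$Km <= 0) stop("state reached -Km; rational term undefined")
  p$jx - p$Vmax * y[1] / (p$Km + y[1])
}

#' @rdname mm_params
#' @param params parameter list from [mm_params()].
#' @param x0 initial substrate concentration (>= 0).
#' @param times output time grid.
#' @export
simulate_michaelis_menten <- function(params = mm_params(), x0 = 0.5,
                                      times = seq(0, 10, by = 0.001)) {
  if (x0 < 0) stop("x0 must be >= 0")
  sim_with_derivs(mm_rhs, x0, times, "x", params)
}

#' Default implicit library for the Michaelis-Menten system
#'
#' Polynomials in x up to degree 2 with at most one xdot factor per
#' term: 1, x, x^2, dx, x*dx, x^2*dx. Contains the implicit form of
#' the true model, jx*Km + (jx - Vmax)*x - Km*dx - x*dx = 0.
#' @export
mm_library_spec <- function() {
  library_spec(states = "x", derivs = "dx", degree = 2)
}

#' @rdname mm_library_spec
#' @export
mm_truth_support <- function() c("1", "x", "dx", "x*dx")

#' @rdname mm_library_spec
#' @return list of admissible implicit supports of the true dynamics
#'   within the degree-2 library: the base relation and its
#'   x-multiple, which encode the same rational right-hand side.
#' @export
mm_truth_family <- function() {
  list(base = c("1", "x", "dx", "x*dx"),
       times_x = c("x", "x^2", "x*dx", "x^2*dx"))
}

#' Yeast glycolysis network (7 states)
#'
#' The Ruoff-lineage glycolytic oscillator: seven metabolite pools with
#' a Hill-type (1 + (x6/K1)^4)^-1 inhibition making the ATP equation
#' rational. Parameter defaults follow the commonly used benchmark
#' values for this model.
#'
#' @param J0,k1,k2,k3,k4,k5,k6,K1,q,N,A,kappa,psi,k kinetic constants.
#' @export
glycolysis_params <- function(J0 = 2.5, k1 = 100, k2 = 6, k3 = 16,
                              k4 = 100, k5 = 1.28, k6 = 12, K1 = 0.52,
                              q = 4, N = 1, A = 4, kappa = 13,
                              psi = 0.1, k = 1.8) {
  list(J0 = J0, k1 = k1, k2 = k2, k3 = k3, k4 = k4, k5 = k5, k6 = k6,
       K1 = K1, q = q, N = N, A = A, kappa = kappa, psi = psi, k = k)
}

glycolysis_rhs <- function(t, y, p) {
  hill <- p$k1 * y[1] * y[6] / (1 + (y[6] / p$K1)^p$q)
  c(p$J0 - hill,
    2 * hill - p$k2 * y[2] * (p$N - y[5]) - p$k6 * y[2] * y[5],
    p$k2 * y[2] * (p$N - y[5]) - p$k3 * y[3] * (p$A - y[6]),
    p$k3 * y[3] * (p$A - y[6]) - p$k4 * y[4] * y[5] - p$kappa * (y[4] - y[7]),
    p$k2 * y[2] * (p$N - y[5]) - p$k4 * y[4] * y[5] - p$k6 * y[2] * y[5],
    -2 * hill + 2 * p$k3 * y[3] * (p$A - y[6]) - p$k5 * y[6],
    p$psi * p$kappa * (y[4] - y[7]) - p$k * y[7])
}

#' @rdname glycolysis_params
#' @param params parameter list from [glycolysis_params()].
#' @param x0 positive initial state (length 7).
#' @param times output time grid.
#' @export
simulate_yeast_glycolysis <- function(params = glycolysis_params(),
                                      x0 = c(1.0, 1.0, 0.1, 0.2, 0.15, 1.0, 0.07),
                                      times = seq(0, 5, by = 0.01)) {
  if (any(x0 <= 0)) stop("x0 must be positive")
  sim_with_derivs(glycolysis_rhs, x0, times, paste0("x", 1:7), params)
}

#' @rdname glycolysis_params
#' @param seed integer seed; draws an initial condition uniformly from
#'   the benchmark ranges used for this model.
#' @export
glycolysis_random_x0 <- function(seed) {
  lo <- c(0.15, 0.19, 0.04, 0.10, 0.08, 0.14, 0.05)
  hi <- c(1.60, 2.16, 0.20, 0.35, 0.30, 2.67, 0.10)
  with_seed(seed, stats::runif(7, lo, hi))
}

#' ATP-equation coefficients of the glycolysis model
#'
#' The sixth state equation in its rational benchmark form
#' dx6 = h1*x1*x6 / (1 + h2*x6^4) + h3*x3 + h4*x3*x6 + h5*x6,
#' expressed from the kinetic constants.
#' @param params parameter list from [glycolysis_params()].
#' @export
glycolysis_h_coefficients <- function(params = glycolysis_params()) {
  with(params, c(h1 = -2 * k1, h2 = K1^-q, h3 = 2 * k3 * A,
                 h4 = -2 * k3, h5 = -k5))
}

#' Implicit library for the glycolysis ATP equation
#'
#' Quadratic monomials in the metabolite pools coupled to the ATP
#' equation (x1 and x3 drive its kinetics, x2 is the pathway
#' intermediate linking them, and x6 is ATP itself), optionally
#' multiplied by the Hill-denominator feature x6q = x6^4 and/or by the
#' single derivative dx6: 60 terms. Multiplying a low-order polynomial
#' basis by the known Hill power is the standard way to keep an
#' implicit library for saturating kinetics small while containing the
#' cleared form of the true equation; restricting the vocabulary to
#' the chemically coupled pools is the same expert trimming used for
#' the trigonometric variables of the mechanical examples.
#' @export
glycolysis_x6_library_spec <- function() {
  library_spec(states = paste0("x", 1:7), derivs = "dx6", degree = 2,
               poly_vars = c("x1", "x2", "x3", "x6"),
               deriv_vars = "dx6", aux_vars = "x6q")
}

#' @rdname glycolysis_x6_library_spec
#' @param data a `ts_data` from [simulate_yeast_glycolysis()].
#' @export
glycolysis_x6_variables <- function(data) {
  stopifnot(inherits(data, "ts_data"))
  cbind(data$X, dx6 = data$Xdot[, "dx6"], x6q = data$X[, "x6"]^4)
}

#' @rdname glycolysis_x6_library_spec
#' @export
glycolysis_x6_truth_support <- function() {
  c("x3", "x6", "dx6", "x1*x6", "x3*x6", "x6*x6q", "x3*x6q",
    "x3*x6*x6q", "dx6*x6q")
}

#' Forced single pendulum on a cart
#'
#' Euler-Lagrange dynamics of a pendulum of mass m and arm length L1
#' mounted on a cart of mass M, with a horizontal force F(t) applied
#' to the cart. States are (phi, s, phidot, sdot) with phi measured
#' from the upright position (the hanging rest state is phi = pi), so
#' trajectories started near phi = 0 fall and explore large angles.
#' Both acceleration equations are rational in cos(phi)^2 through the
#' shared inertia denominator M + m - m*cos(phi)^2.
#'
#' @param M cart mass, @param m pendulum mass, @param L1 arm length,
#' @param g gravity. Defaults: unit parameters except gravity.
#' @export
cartpole_params <- function(M = 1, m = 1, L1 = 1, g = 9.81) {
  if (min(M, m, L1, g) <= 0) stop("all parameters must be positive")
  list(M = M, m = m, L1 = L1, g = g)
}

cartpole_rhs_factory <- function(forcing) {
  function(t, y, p) {
    phi <- y[1]; phidot <- y[3]
    F <- forcing(t)
    s <- sin(phi); c <- cos(phi)
    D <- p$M + p$m - p$m * c^2
    c(phidot,
      y[4],
      ((p$M + p$m) * p$g * s - F * c - p$m * p$L1 * phidot^2 * s * c) /
        (p$L1 * D),
      (F + p$m * p$L1 * phidot^2 * s - p$m * p$g * s * c) / D)
  }
}

#' @rdname cartpole_params
#' @param params parameter list from [cartpole_params()].
#' @param x0 initial state (phi, s, phidot, sdot).
#' @param forcing function(t) returning the horizontal force F.
#' @param times output time grid.
#' @export
simulate_cart_pendulum <- function(params = cartpole_params(),
                                   x0 = c(0.3, 0, 1, 0),
                                   forcing = function(t) -0.2 + 0.5 * sin(6 * t),
                                   times = seq(0, 16, by = 0.001)) {
  rhs <- cartpole_rhs_factory(forcing)
  sim_with_derivs(rhs, x0, times, c("phi", "s", "phidot", "sdot"),
                  params, control = function(t) c(F = forcing(t)),
                  control_names = "F")
}

#' @rdname cartpole_params
#' @param data a `ts_data` from [simulate_cart_pendulum()].
#' @return total mechanical energy at every sample.
#' @export
cart_pendulum_energy <- function(data, params = cartpole_params()) {
  X <- data$X
  with(params,
       0.5 * (M + m) * X[, "sdot"]^2 +
         m * L1 * X[, "sdot"] * X[, "phidot"] * cos(X[, "phi"]) +
         0.5 * m * L1^2 * X[, "phidot"]^2 +
         m * g * L1 * cos(X[, "phi"]))
}

#' Implicit trig + polynomial library for the cart-pendulum
#'
#' Polynomials up to degree 2 in phidot and the control F (F at most
#' linear), trigonometric products in phi up to total degree 2, and at
#' most one factor of the targeted acceleration per term, with
#' acceleration-bearing terms restricted to even-trig-degree
#' multipliers (the inertia denominator is a quadratic form in the
#' direction cosines): 28 terms per row. Each acceleration equation is
#' fitted with only its own
#' derivative in the vocabulary, so every implicit fit can be solved
#' into an explicit rational right-hand side; the angle is the only
#' variable entering trigonometrically, which keeps the library well
#' conditioned.
#'
#' @param row which acceleration equation the library targets:
#'   "phidot" or "sdot".
#' @export
cartpole_library_spec <- function(row = c("phidot", "sdot")) {
  row <- match.arg(row)
  library_spec(states = c("phi", "s", "phidot", "sdot"),
               controls = "F", degree = 2,
               poly_vars = c("phidot", "F"), var_caps = c(F = 1),
               trig_vars = "phi", trig_degree = 2,
               deriv_vars = paste0("d", row), deriv_total = 1,
               deriv_poly_cap = 0, deriv_trig_even = TRUE)
}

#' @rdname cartpole_library_spec
#' @return list with the true implicit supports of the phidot and sdot
#'   acceleration equations.
#' @export
cartpole_truth_support <- function() {
  list(
    phidot = c("dphidot", "cos(phi)^2*dphidot", "sin(phi)",
               "F*cos(phi)", "phidot^2*sin(phi)*cos(phi)"),
    sdot = c("dsdot", "cos(phi)^2*dsdot", "F", "phidot^2*sin(phi)",
             "sin(phi)*cos(phi)")
  )
}

#' @rdname cartpole_library_spec
#' @param row "phidot" or "sdot".
#' @return the default candidate left-hand sides for one acceleration
#'   row: the acceleration times each trigonometric factor up to
#'   degree 2.
#' @export
cartpole_candidates <- function(row = c("phidot", "sdot")) {
  row <- match.arg(row)
  dv <- paste0("d", row)
  c(dv, paste0(c("sin(phi)*cos(phi)*", "cos(phi)^2*"), dv))
}

#' Mounted double pendulum
#'
#' Two rigid arms with distributed mass (centre-of-mass offsets a1, a2
#' and moments of inertia I1, I2), the first mounted at a fixed pivot,
#' with optional viscous joint friction. Angles are measured from the
#' upright position, so the hanging equilibrium is at (pi, pi). The
#' Euler-Lagrange equations are rational in the angles through the
#' coupled inertia matrix, and chaotic for generic initial conditions.
#'
#' @param m1,m2 arm masses.
#' @param L1 distance from the base pivot to the second joint.
#' @param a1,a2 pivot-to-centre-of-mass distances.
#' @param I1,I2 centre-of-mass moments of inertia (uniform-rod
#'   defaults m*L^2/12 with L = 1).
#' @param g gravity.
#' @param k1,k2 viscous joint friction constants.
#' @export
dpend_params <- function(m1 = 1, m2 = 1, L1 = 1, a1 = 0.5, a2 = 0.5,
                         I1 = 1 / 12, I2 = 1 / 12, g = 9.81,
                         k1 = 7.2484e-4, k2 = 1.6522e-4) {
  list(m1 = m1, m2 = m2, L1 = L1, a1 = a1, a2 = a2, I1 = I1, I2 = I2,
       g = g, k1 = k1, k2 = k2)
}

dpend_coefs <- function(p) {
  list(a1 = p$I1 + p$m1 * p$a1^2 + p$m2 * p$L1^2,
       a2 = p$I2 + p$m2 * p$a2^2,
       b = p$m2 * p$L1 * p$a2,
       g1 = (p$m1 * p$a1 + p$m2 * p$L1) * p$g,
       g2 = p$m2 * p$a2 * p$g)
}

dpend_rhs_factory <- function(friction) {
  function(t, y, p) {
    cf <- dpend_coefs(p)
    d <- y[1] - y[2]
    cd <- cos(d); sd <- sin(d)
    t1 <- if (friction) -p$k1 * y[3] else 0
    t2 <- if (friction) -p$k2 * y[4] else 0
    # mass matrix [a1, b*cd; b*cd, a2] %*% (ddphi1, ddphi2) = rhs
    r1 <- t1 - cf$b * sd * y[4]^2 + cf$g1 * sin(y[1])
    r2 <- t2 + cf$b * sd * y[3]^2 + cf$g2 * sin(y[2])
    det <- cf$a1 * cf$a2 - (cf$b * cd)^2
    c(y[3], y[4],
      (cf$a2 * r1 - cf$b * cd * r2) / det,
      (cf$a1 * r2 - cf$b * cd * r1) / det)
  }
}

#' @rdname dpend_params
#' @param params parameter list from [dpend_params()].
#' @param x0 initial state (phi1, phi2, phi1dot, phi2dot).
#' @param times output time grid.
#' @param friction include viscous joint friction (default TRUE).
#' @export
simulate_double_pendulum <- function(params = dpend_params(),
                                     x0 = c(pi + 1.2, pi - 0.6, 0, 0),
                                     times = seq(0, 10, by = 0.001),
                                     friction = TRUE) {
  rhs <- dpend_rhs_factory(friction)
  sim_with_derivs(rhs, x0, times,
                  c("phi1", "phi2", "phi1dot", "phi2dot"), params)
}

#' @rdname dpend_params
#' @param data a `ts_data` from [simulate_double_pendulum()].
#' @return total mechanical energy at every sample.
#' @export
double_pendulum_energy <- function(data, params = dpend_params()) {
  cf <- dpend_coefs(params)
  X <- data$X
  0.5 * cf$a1 * X[, "phi1dot"]^2 + 0.5 * cf$a2 * X[, "phi2dot"]^2 +
    cf$b * X[, "phi1dot"] * X[, "phi2dot"] * cos(X[, "phi1"] - X[, "phi2"]) +
    cf$g1 * cos(X[, "phi1"]) + cf$g2 * cos(X[, "phi2"])
}

#' Implicit library for the double pendulum
#'
#' Polynomials up to degree 2 in the angular velocities, trig products
#' of the two angles up to total degree 2, one acceleration factor per
#' term (270 terms). Only the rotation angles enter trigonometrically.
#' @export
dpend_library_spec <- function() {
  library_spec(states = c("phi1", "phi2", "phi1dot", "phi2dot"),
               degree = 2, poly_vars = c("phi1dot", "phi2dot"),
               trig_vars = c("phi1", "phi2"), trig_degree = 2,
               deriv_vars = c("dphi1dot", "dphi2dot"), deriv_total = 1,
               deriv_trig_even = TRUE)
}

#' @rdname dpend_library_spec
#' @return true implicit support of the first acceleration equation
#'   (frictionless form).
#' @export
dpend_truth_support <- function() {
  c("dphi1dot", "cos(phi1)*cos(phi2)*dphi2dot",
    "sin(phi1)*sin(phi2)*dphi2dot", "phi2dot^2*sin(phi1)*cos(phi2)",
    "phi2dot^2*cos(phi1)*sin(phi2)", "sin(phi1)")
}

#' Add seeded Gaussian measurement noise
#'
#' Adds i.i.d. Gaussian noise of standard deviation `sigma` (in state
#' units) to the selected channels. With `sigma = 0` the input is
#' returned unchanged; the same seed always reproduces the same noise.
#' Derivative channels are left untouched unless explicitly requested:
#' whether derivatives are re-computed from noisy states or treated as
#' independently noisy measurements is a per-benchmark choice.
#'
#' @param x a `ts_data`, `field_data`, or numeric matrix/vector.
#' @param sigma noise standard deviation (>= 0).
#' @param seed integer seed.
#' @param channels for `ts_data`: subset of c("states", "derivs",
#'   "controls").
#' @export
add_noise <- function(x, sigma, seed = 1, channels = "states") {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(x)
  UseMethod("add_noise")
}

#' @export
add_noise.ts_data <- function(x, sigma, seed = 1, channels = "states") {
  slots <- c(states = "X", derivs = "Xdot", controls = "U")
  bad <- setdiff(channels, names(slots))
  if (length(bad)) stop("unknown channels: ", paste(bad, collapse = ", "))
  with_seed(seed, {
    for (ch in channels) {
      s <- slots[[ch]]
      if (!is.null(x[[s]]))
        x[[s]] <- x[[s]] + stats::rnorm(length(x[[s]]), 0, sigma)
    }
  })
  x
}

#' @export
add_noise.field_data <- function(x, sigma, seed = 1, channels = "states") {
  with_seed(seed, {
    x$u <- x$u + stats::rnorm(length(x$u), 0, sigma)
  })
  x
}

#' @export
add_noise.default <- function(x, sigma, seed = 1, channels = "states") {
  with_seed(seed, x + stats::rnorm(length(x), 0, sigma))
}
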