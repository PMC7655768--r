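# Shared fixtures and independent oracles used across the suite.

# direct pointwise evaluation of a term, independent of the library
# machinery: multiply out powers and trig factors by hand
eval_term_pointwise <- function(term, row) {
  val <- 1
  for (k in seq_along(term$powers)) {
    atom <- names(term$powers)[k]
    p <- term$powers[[k]]
    m <- regmatches(atom, regexec("^(sin|cos)\\((.+)\\)$", atom))[[1]]
    v <- if (length(m) == 3) {
      if (m[2] == "sin") sin(row[[m[3]]]) else cos(row[[m[3]]])
    } else row[[atom]]
    val <- val * v^p
  }
  val
}

# exhaustive best-subset search over supports of size <= kmax,
# returning the support with the smallest residual sum of squares
best_subset_support <- function(A, b, kmax = 2) {
  p <- ncol(A)
  best <- NULL
  best_rss <- Inf
  subsets <- list()
  for (k in 1:kmax) subsets <- c(subsets, utils::combn(p, k, simplify = FALSE))
  for (s in subsets) {
    fit <- stats::lm.fit(A[, s, drop = FALSE], b)
    rss <- sum(fit$residuals^2)
    # prefer strictly better fits; smaller support wins near-ties
    if (rss < best_rss * (1 - 1e-10)) {
      best <- s
      best_rss <- rss
    }
  }
  sort(best)
}

# small noiseless Michaelis-Menten data set shared by several tests
mm_quick_data <- function(dt = 0.01, T = 10, x0 = 0.5) {
  simulate_michaelis_menten(mm_params(), x0, seq(0, T, by = dt))
}

# independent hand-written evaluation of the glycolysis right-hand
# side (hill term expanded differently from the simulator's code path)
glycolysis_rhs_oracle <- function(y, p) {
  denom <- 1 + y[6]^p$q / p$K1^p$q
  v1 <- p$k1 * y[1] * y[6] / denom
  v2 <- p$k2 * y[2] * (p$N - y[5])
  v3 <- p$k3 * y[3] * (p$A - y[6])
  v4 <- p$k4 * y[4] * y[5]
  v6 <- p$k6 * y[2] * y[5]
  vk <- p$kappa * (y[4] - y[7])
  c(p$J0 - v1,
    2 * v1 - v2 - v6,
    v2 - v3,
    v3 - v4 - vk,
    v2 - v4 - v6,
    -2 * v1 + 2 * v3 - p$k5 * y[6],
    p$psi * vk - p$k * y[7])
}

# minimal single-variable term (tests poke the library container
# directly in a couple of places)
new_term_for_test <- function(var) {
  sindypi:::new_term(stats::setNames(1L, var))
}

# degree-2 enzyme-kinetics library without the x^2*dx column: the
# implicit relation is then unique, which makes single-fit tests
# deterministic (the full library admits the x-multiple family)
mm_unique_spec <- function(deriv_poly_cap = 1) {
  library_spec(states = "x", derivs = "dx", degree = 2,
               deriv_poly_cap = deriv_poly_cap)
}
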