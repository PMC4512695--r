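# Independent brute-force oracles used against the closed forms.

# Double quadrature of kern(t1, t2) over [0, t]^2, splitting the inner
# integral at the |t1 - t2| kink.
brute_double_integral <- function(t, kern) {
  stats::integrate(Vectorize(function(t1) {
    stats::integrate(function(t2) kern(t1, t2), 0, t1, rel.tol = 1e-11)$value +
      stats::integrate(function(t2) kern(t1, t2), t1, t, rel.tol = 1e-11)$value
  }), 0, t, rel.tol = 1e-10)$value
}

ou_kernel <- function(D, tau_c) {
  function(t1, t2) D * exp(-abs(t1 - t2) / tau_c)
}

z_kernel <- function(D, tau_c, gamma, t) {
  function(t1, t2) exp(-gamma * (2 * t - t1 - t2)) * D * exp(-abs(t1 - t2) / tau_c)
}

# Quadrant probability P(X > 0, Y > 0) of a standard bivariate normal with
# correlation rho, by trapezoid integration of the density on a grid.
binorm_orthant <- function(rho, lim = 6, n = 600) {
  x <- seq(0, lim, length.out = n)
  f <- outer(x, x, function(a, b)
    exp(-(a^2 - 2 * rho * a * b + b^2) / (2 * (1 - rho^2))) /
      (2 * pi * sqrt(1 - rho^2)))
  w <- rep(1, n); w[c(1, n)] <- 0.5
  h <- x[2] - x[1]
  as.numeric(t(w) %*% f %*% w) * h^2
}

# Two-piece adaptive quadrature of a density over (0, Inf), split at a
# finite interior point to protect narrow peaks.
quad_positive <- function(f, split) {
  stats::integrate(f, 0, split, rel.tol = 1e-10)$value +
    stats::integrate(f, split, Inf, rel.tol = 1e-10)$value
}

fig2a_model <- function() {
  logistic_model(1, gamma = 1, epsilon = 0.5,
                 noise = noise_params(map_stationary_beta(500, 1, 0.01), 0.01))
}

fig2b_model <- function() {
  logistic_model(1, gamma = 1, epsilon = 0.5,
                 noise = noise_params(map_stationary_beta(50, 1, 0.01), 0.01))
}

fig2c_model <- function() {
  logistic_model(1, gamma = 0.5, epsilon = 0.5,
                 noise = noise_params(map_stationary_beta(5, 0.5, 0.01), 0.01))
}
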