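test_that("integrated-noise variance matches its brute-force double integral", {
  expect_equal(gamma_sq(0, noise_params(3, 0.2)), 0)
  expect_error(gamma_sq(-1, noise_params(1, 1)), ">= 0")
  # quadratic ballistic regime t << tau_c
  np <- noise_params(2, 5)
  expect_equal(gamma_sq(0.01, np), 2 * 0.01^2, tolerance = 1e-3)
  for (p in list(c(2, 0.3), c(1, 1), c(100, 0.01))) {
    np <- noise_params(p[1], p[2])
    for (t in c(0.25, 1.3)) {
      oracle <- brute_double_integral(t, ou_kernel(p[1], p[2]))
      expect_equal(gamma_sq(t, np), oracle, tolerance = 1e-8)
    }
  }
})

test_that("alpha(t) rises monotonically from 0 to the white-noise plateau D*tau_c", {
  np <- noise_params(3, 0.7)
  tt <- c(1e-6, 0.1, 0.5, 1, 5, 50, 500)
  a <- alpha_t(tt, np)
  expect_true(all(diff(a) > 0))
  expect_true(all(a >= 0 & a < 3 * 0.7))
  expect_equal(a[length(a)], 3 * 0.7, tolerance = 1e-2)
  expect_equal(alpha_t(0, np), 0)
})

test_that("linear density is a normalized log-normal with the stated moments", {
  m <- linear_model(1, 0, noise_params(1, 1))
  for (t in c(0.5, 2)) {
    norm <- stats::integrate(function(c) linear_pdf(c, t, m), 0, Inf,
                             rel.tol = 1e-10)$value
    expect_equal(norm, 1, tolerance = 1e-6)
    qmean <- stats::integrate(function(c) c * linear_pdf(c, t, m), 0, Inf,
                              rel.tol = 1e-10)$value
    mo <- linear_moments(t, m)
    expect_equal(qmean, mo$mean, tolerance = 1e-6)
    expect_equal(qmean, exp(alpha_t(t, m$noise) * t), tolerance = 1e-6)
    qm2 <- stats::integrate(function(c) c^2 * linear_pdf(c, t, m), 0, Inf,
                            rel.tol = 1e-10)$value
    expect_equal(sqrt(qm2 - qmean^2), mo$dispersion, tolerance = 1e-6)
    # dispersion identity (Delta C / mean)^2 + 1 = e^(2 alpha t)
    expect_equal((mo$dispersion / mo$mean)^2 + 1,
                 exp(2 * alpha_t(t, m$noise) * t), tolerance = 1e-10)
  }
  expect_error(linear_pdf(-1, 1, m), "> 0")
})

test_that("constant drift shifts the linear law as gamma + alpha", {
  m <- linear_model(2, gamma = -0.4, noise = noise_params(100, 0.01))
  mo <- linear_moments(c(1, 2), m)
  a <- alpha_t(c(1, 2), m$noise)
  expect_equal(mo$mean, 2 * exp((-0.4 + a) * c(1, 2)), tolerance = 1e-12)
  # negative mean growth rate, |gamma| < alpha: mean grows, mode collapses
  expect_gt(mo$mean[2], mo$mean[1])
  mode_of <- function(t) exp(-0.4 * t - gamma_sq(t, m$noise)) * 2
  expect_lt(mode_of(2), mode_of(1))
  # quadrature mean of the shifted density agrees
  qmean <- stats::integrate(function(c) c * linear_pdf(c, 1, m), 0, Inf,
                            rel.tol = 1e-10)$value
  expect_equal(qmean, mo$mean[1], tolerance = 1e-6)
})

test_that("filtered-noise variance matches its brute-force oracle and limits", {
  sets <- list(c(D = 100, tau = 0.01, g = 1),
               c(D = 1, tau = 1, g = 0.7),
               c(D = 4, tau = 0.3, g = 2))
  for (p in sets) {
    m <- logistic_model(1, p[["g"]], 0.5, noise_params(p[["D"]], p[["tau"]]))
    expect_equal(z_var(0, m), 0, tolerance = 1e-12)
    for (t in c(0.1, 1, 5)) {
      oracle <- brute_double_integral(t, z_kernel(p[["D"]], p[["tau"]], p[["g"]], t))
      expect_equal(z_var(t, m), oracle, tolerance = 1e-8)
    }
    lim <- p[["D"]] / (p[["g"]] * (p[["g"]] + 1 / p[["tau"]]))
    expect_equal(z_var(50 / p[["g"]], m), lim, tolerance = 1e-10)
  }
  # removable singularity gamma * tau_c = 1
  ms <- logistic_model(1, 2, 0.5, noise_params(1, 0.5))
  for (t in c(0.3, 0.7, 2)) {
    oracle <- brute_double_integral(t, z_kernel(1, 0.5, 2, t))
    expect_equal(z_var(t, ms), oracle, tolerance = 1e-8)
  }
  expect_true(is.infinite(beta_of(0, ms)))
})

test_that("stationary-beta mapping is an exact inverse and monotone", {
  expect_equal(map_stationary_beta(500, gamma = 1, tau_c = 0.01), 101 / 1000)
  for (b in c(5, 50, 500)) {
    D <- map_stationary_beta(b, gamma = 1, tau_c = 0.01)
    m <- logistic_model(1, 1, 0.5, noise_params(D, 0.01))
    expect_equal(stationary_beta(m), b, tolerance = 1e-12)
    expect_equal(beta_of(200, m), b, tolerance = 1e-6)
  }
  Ds <- vapply(c(5, 50, 500), map_stationary_beta, numeric(1),
               gamma = 1, tau_c = 0.01)
  expect_true(all(diff(Ds) < 0))
})

test_that("logistic density normalizes, peaks at C*, and concentrates as beta -> infinity", {
  for (mfun in list(fig2a_model, fig2b_model, fig2c_model)) {
    m <- mfun()
    for (t in c(0.4, 2, 4)) {
      f <- function(c) logistic_pdf(c, t, m, mode = "stationary_beta")
      expect_equal(quad_positive(f, carrying_capacity(m)), 1, tolerance = 1e-6)
      g <- function(c) logistic_pdf(c, t, m)
      expect_equal(quad_positive(g, carrying_capacity(m)), 1, tolerance = 1e-6)
    }
  }
  m <- fig2a_model()
  cg <- seq(0.2, 4, 0.01)
  mode_at <- cg[which.max(logistic_pdf(cg, 4, m))]
  expect_lt(abs(mode_at - 2), 0.1)
  # beta -> infinity: mass concentrates on the deterministic trajectory 1/A
  mbig <- logistic_model(1, 1, 0.5, noise_params(1e-6, 0.01))
  det <- 1 / logistic_A(2, mbig)
  mass <- stats::integrate(function(c) logistic_pdf(c, 2, mbig),
                           det - 0.05, det + 0.05, rel.tol = 1e-9)$value
  expect_gt(mass, 0.999)
  expect_error(logistic_pdf(0, 1, m), "> 0")
  expect_error(logistic_pdf(1, 0, m), "> 0")
})

test_that("logistic CDF agrees with direct quadrature of the density", {
  m <- fig2b_model()
  for (t in c(0.4, 4)) {
    for (cc in c(0.5, 1.5, 3)) {
      direct <- stats::integrate(function(x) logistic_pdf(x, t, m), 0, cc,
                                 rel.tol = 1e-10)$value
      expect_equal(logistic_cdf(cc, t, m), direct, tolerance = 1e-7)
    }
  }
})

test_that("logistic mean saturates at the carrying capacity for weak noise", {
  m <- fig2a_model()
  expect_equal(mean_limits(m)$large_beta, 2)
  expect_equal(logistic_mean(10, m, mode = "stationary_beta"), 2, tolerance = 0.02)
  expect_equal(logistic_mean(10, m), 2, tolerance = 0.02)
  m0 <- logistic_model(1, 1, 0, noise_params(1, 1))
  expect_error(mean_limits(m0), "epsilon = 0")
})

test_that("strong-noise mean diverges logarithmically as epsilon vanishes", {
  m <- logistic_model(1, 1, 0.5, noise_params(map_stationary_beta(2, 1, 0.01), 0.01))
  lim <- mean_limits(m, eps_grid = c(0.5, 0.1, 0.02), t_eval = 10)
  expect_true(all(diff(lim$small_beta$means) > 0))  # epsilon decreasing along grid
  expect_true(lim$small_beta$diverges_as_eps_to_zero)
})

test_that("closed-form chi agrees qualitatively with the finite-difference oracle", {
  m <- fig2b_model()
  cg <- seq(0.15, 8, 0.025)
  for (t in c(0.4, 0.8)) {
    pc <- local_growth_rate_chi(cg, t, m)
    pn <- numeric_chi(cg, t, m)
    expect_gt(mean(sign(pc$chi) == sign(pn$chi)), 0.98)
    cross <- function(p) p$c[which(diff(sign(p$chi)) != 0)[1]]
    expect_lt(abs(cross(pc) - cross(pn)), 0.1)
  }
  # chi decreases with C on its positive small-C branch below the carrying
  # capacity (the branch shown in the field's growth-variability plots;
  # between its zero crossings chi is negative and rises back toward the
  # advancing density peak)
  for (mfun in list(fig2a_model, fig2b_model, fig2c_model)) {
    mm <- mfun()
    cs <- seq(0.2, 0.95 * carrying_capacity(mm), length.out = 200)
    chi <- local_growth_rate_chi(cs, 0.8, mm)$chi
    first_cross <- which(chi <= 0)[1]
    expect_gt(first_cross, 3)                  # a positive branch exists
    expect_true(all(diff(chi[seq_len(first_cross - 1)]) < 0))
  }
  expect_error(local_growth_rate_chi(c(-1, 1), 1, m), "> 0")
})

test_that("growth of the mean population slows to zero as the PDF becomes stationary", {
  m <- fig2a_model()
  r1 <- mean_growth_rate(0.5, m)
  r4 <- mean_growth_rate(4, m)
  r10 <- mean_growth_rate(10, m)
  expect_gt(r1, r4)
  expect_gt(r4, r10)
  expect_lt(abs(r10), 1e-3)
  # cross-check against a manual log-mean difference on a finer stencil
  manual <- (log(logistic_mean(4.01, m)) - log(logistic_mean(3.99, m))) / 0.02
  expect_equal(mean_growth_rate(4, m), manual, tolerance = 1e-3)
})
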