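test_that("model constructors validate their parameters", {
  np <- noise_params(1, 1)
  expect_error(linear_model(0, 0, np), "C0")
  expect_error(logistic_model(1, 0, 0.5, np), "gamma")
  expect_error(logistic_model(1, 1, -1, np), "epsilon")
  expect_equal(carrying_capacity(logistic_model(1, 1, 0.5, np)), 2)
  expect_equal(carrying_capacity(logistic_model(1, 3, 0, np)), Inf)
})

test_that("noise-free linear model is exactly exponential", {
  m0 <- linear_model(2, gamma = 0, noise = noise_params(0, 1))
  e0 <- simulate_linear(m0, seq(0, 3, 0.5), 4, seed = 1)
  expect_true(all(e0$values == 2))
  mg <- linear_model(1, gamma = -0.3, noise = noise_params(0, 1))
  eg <- simulate_linear(mg, seq(0, 3, 0.5), 2, seed = 1)
  expect_equal(eg$values[1, ], exp(-0.3 * eg$times), tolerance = 1e-12)
})

test_that("linear ensemble mean tracks C0*exp(alpha*t) in the white-noise regime", {
  # tau_c = 0.01, D = 100
  m <- linear_model(1, 0, noise_params(100, 0.01))
  tt <- c(0.05, 0.15, 0.25)
  ens <- simulate_linear(m, tt, 4000, seed = 13)
  for (j in seq_along(tt)) {
    x <- ens$values[, j]
    target <- exp(alpha_t(tt[j], m$noise) * tt[j])
    expect_lt(abs(mean(x) - target), 4 * sd(x) / sqrt(length(x)))
  }
})

test_that("linear ensemble mean matches exp(<Gamma^2>/2) from the quadrature oracle", {
  # tau_c = 1, D = 1, t = 1: <Gamma^2> by brute-force double integration
  gsq_oracle <- brute_double_integral(1, ou_kernel(1, 1))
  m <- linear_model(1, 0, noise_params(1, 1))
  ens <- simulate_linear(m, 1, 5000, seed = 17)
  x <- ens$values[, 1]
  expect_lt(abs(mean(x) - exp(gsq_oracle / 2)), 4 * sd(x) / sqrt(length(x)))
})

test_that("white-noise limit depends only on D*tau_c", {
  t <- 0.25
  e1 <- simulate_linear(linear_model(1, 0, noise_params(100, 0.01)),
                        t, 1500, seed = 19)
  e2 <- simulate_linear(linear_model(1, 0, noise_params(1000, 0.001)),
                        t, 1500, seed = 23)
  ks <- suppressWarnings(stats::ks.test(e1$values[, 1], e2$values[, 1]))
  expect_gt(ks$p.value, 1e-3)
})

test_that("noise-free logistic converges to the carrying capacity", {
  m <- logistic_model(1, 1, 0.5, noise_params(0, 1))
  for (meth in c("heun", "inverse")) {
    e <- simulate_logistic(m, c(0, 1, 20), 1, seed = 1, method = meth)
    expect_lt(abs(e$values[1, 3] - 2), 1e-6)
    expect_true(all(e$values > 0))
  }
})

test_that("weak-noise logistic histogram peaks near the carrying capacity", {
  m <- fig2a_model()  # beta* = 500, C* = 2
  e <- simulate_logistic(m, c(0, 4), 800, seed = 29, method = "heun")
  h <- ensemble_histogram(e, 4, breaks = seq(0, 4, 0.1))
  peak <- h$bin_left[which.max(h$density)]
  expect_lt(abs(peak + 0.05 - 2), 0.25)
  expect_equal(sum(h$density * (h$bin_right - h$bin_left)), 1, tolerance = 1e-9)
})

test_that("Heun integration is converged in dt and agrees with the inverse route", {
  m <- logistic_model(1, 1, 0.5, noise_params(map_stationary_beta(50, 1, 0.1), 0.1))
  tt <- c(1, 2)
  e1 <- simulate_logistic(m, tt, 400, seed = 31, dt = 0.01)
  e2 <- simulate_logistic(m, tt, 400, seed = 31, dt = 0.005)
  expect_lt(max(abs(colMeans(e1$values) / colMeans(e2$values) - 1)), 0.01)
  e3 <- simulate_logistic(m, tt, 400, seed = 31, dt = 0.005, method = "inverse")
  expect_lt(max(abs(e2$values - e3$values) / e3$values), 0.02)
})

test_that("small-noise logistic ensembles collapse onto the deterministic curve", {
  tt <- seq(0.5, 4, 0.5)
  det <- 1 / (exp(-tt) / 1 + 0.5 * (1 - exp(-tt)))  # logistic solution, C* = 2
  dev <- vapply(c(0.05, 0.005), function(D) {
    m <- logistic_model(1, 1, 0.5, noise_params(D, 0.1))
    e <- simulate_logistic(m, tt, 200, seed = 37)
    max(abs(colMeans(e$values) - det))
  }, numeric(1))
  expect_lt(dev[2], dev[1])
  expect_lt(dev[2], 0.05)
})

test_that("blow-up replicates are flagged, frozen at the cap, and excluded from histograms", {
  # epsilon + g_c < 0 persists easily: strong slow noise, weak regulation
  m <- logistic_model(1, 1, 0.05, noise_params(4, 2))
  e <- simulate_logistic(m, c(0.5, 1, 3), 300, seed = 41, cap = 1000, method = "heun")
  expect_gt(sum(e$diverged), 0)
  expect_true(all(is.finite(e$values)))
  expect_true(all(e$values[e$diverged, 3] <= 1000))
  expect_true(all(!is.na(e$t_diverged[e$diverged])))
  frozen <- which(e$diverged & e$t_diverged <= 1)
  expect_true(all(e$values[frozen, 2] == e$values[frozen, 3]))
  h <- ensemble_histogram(e, 3)
  expect_equal(attr(h, "excluded"), sum(e$diverged & e$t_diverged <= 3))
  expect_equal(sum(h$density * (h$bin_right - h$bin_left)), 1, tolerance = 1e-9)
})

test_that("ensemble_histogram handles delta and uniform inputs", {
  m <- linear_model(1, 0, noise_params(1, 1))
  e <- simulate_linear(m, c(0, 1), 50, seed = 43)
  h0 <- ensemble_histogram(e, 0, breaks = seq(0.5, 1.5, 0.1))
  expect_equal(sum(h0$density > 0), 1)   # delta initial condition: one bin
  fake <- list(times = 1, values = matrix(seq(0.0005, 1, 0.001), ncol = 1),
               diverged = rep(FALSE, 1000), t_diverged = rep(NA_real_, 1000))
  hu <- ensemble_histogram(fake, 1, breaks = seq(0, 1, 0.25))
  expect_equal(hu$density, rep(1, 4), tolerance = 1e-9)
  expect_error(ensemble_histogram(e, 0.123), "not on the ensemble")
})

test_that("coupled system relaxes to the deterministic fixed point and steady state", {
  m0 <- coupled_model(1, G0 = 0.5, gamma = 1, epsilon = 0.5,
                      noise = noise_params(0, 1))
  e0 <- simulate_coupled(m0, c(5, 20), 1, seed = 1)
  expect_lt(abs(e0$values[1, 2] - 2), 1e-3)          # C -> C* = gamma/epsilon
  expect_lt(abs(e0$growth_input[1, 2] - 0), 1e-3)    # G -> gamma - epsilon*C* = 0

  m1 <- coupled_model(1, G0 = 0.5, gamma = 1, epsilon = 0.5,
                      noise = noise_params(0.05, 0.5))
  e1 <- simulate_coupled(m1, seq(0, 40, 0.5), 60, seed = 2)
  late <- e1$growth_input[, e1$times >= 20]
  dG <- (late[, ncol(late)] - late[, 1]) / 20        # time-averaged dG/dt
  expect_lt(abs(mean(dG)), 0.01)
})

test_that("coupled model tracks the reduced logistic model on shared noise", {
  track_err <- function(gam, eps) {
    tt <- seq(0, 10, 0.5)
    mc <- coupled_model(1, G0 = gam - eps, gamma = gam, epsilon = eps,
                        noise = noise_params(0.005, 1))
    mr <- logistic_model(1, gam, eps, noise_params(0.005, 1))
    ec <- simulate_coupled(mc, tt, 20, seed = 5, dt = 0.005)
    er <- simulate_logistic(mr, tt, 20, seed = 5, dt = 0.005)
    max(abs(ec$values - er$values) / pmax(er$values, 1e-9))
  }
  err_slow <- track_err(0.3, 0.15)  # G relaxation fast relative to dynamics
  err_fast <- track_err(3, 1.5)
  expect_lt(err_slow, err_fast)
  expect_lt(err_slow, 0.5)
})
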