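#' Model parameter constructors
#'
#' Three growth models share the colored-noise growth rate \eqn{g_c(t)}:
#'
#' * **linear**: \eqn{dC/dt = (\gamma + g_c) C}, multiplicative noise on an
#'   exponential grower; `gamma` is an optional constant drift (may be
#'   negative).
#' * **logistic** (reduced self-regulation model):
#'   \eqn{dC/dt = \gamma C - (\epsilon + g_c) C^2}, where `gamma` is the
#'   constitutive growth input and `epsilon` the coherent part of the
#'   self-regulation; the deterministic carrying capacity is
#'   \eqn{C_* = \gamma/\epsilon}.
#' * **coupled**: the full system \eqn{dC/dt = G C},
#'   \eqn{dG/dt = \gamma - (\epsilon + g_c) C - G}, whose quasi-steady
#'   growth input \eqn{G \approx \gamma - (\epsilon+g_c)C} reduces to the
#'   logistic model.
#'
#' @param C0 initial population, `> 0`.
#' @param gamma constant growth-rate part (linear model, any sign,
#'   default 0) or constitutive growth input (logistic/coupled, `> 0`).
#' @param epsilon coherent self-regulation, `>= 0`.
#' @param noise a [noise_params()] object.
#' @param G0 initial growth input for the coupled model.
#' @return A `linear_model`, `logistic_model` or `coupled_model` object.
#' @examples
#' m <- logistic_model(C0 = 1, gamma = 1, epsilon = 0.5,
#'                     noise = noise_params(D = 0.101, tau_c = 0.01))
#' carrying_capacity(m)
#' @export
linear_model <- function(C0, gamma = 0, noise) {
  stopifnot(inherits(noise, "noise_params"))
  if (!is.numeric(C0) || length(C0) != 1L || C0 <= 0)
    stop("`C0` must be a single number > 0", call. = FALSE)
  structure(list(C0 = as.numeric(C0), gamma = as.numeric(gamma), noise = noise),
            class = "linear_model")
}

#' @rdname linear_model
#' @export
logistic_model <- function(C0, gamma, epsilon, noise) {
  stopifnot(inherits(noise, "noise_params"))
  if (!is.numeric(C0) || length(C0) != 1L || C0 <= 0)
    stop("`C0` must be a single number > 0", call. = FALSE)
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)
    stop("`gamma` must be a single number > 0", call. = FALSE)
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon < 0)
    stop("`epsilon` must be a single number >= 0", call. = FALSE)
  structure(list(C0 = as.numeric(C0), gamma = as.numeric(gamma),
                 epsilon = as.numeric(epsilon), noise = noise),
            class = "logistic_model")
}

#' @rdname linear_model
#' @export
coupled_model <- function(C0, G0, gamma, epsilon, noise) {
  m <- logistic_model(C0, gamma, epsilon, noise)
  m$G0 <- as.numeric(G0)
  class(m) <- "coupled_model"
  m
}

#' @rdname linear_model
#' @param model a `logistic_model` or `coupled_model`.
#' @export
carrying_capacity <- function(model) {
  if (model$epsilon <= 0) return(Inf)
  model$gamma / model$epsilon
}

#' @export
print.linear_model <- function(x, ...) {
  cat(sprintf("linear multiplicative-noise model: C0 = %g, gamma = %g\n",
              x$C0, x$gamma))
  print(x$noise); invisible(x)
}

#' @export
print.logistic_model <- function(x, ...) {
  cat(sprintf("stochastic logistic model: C0 = %g, gamma = %g, epsilon = %g (C* = %g)\n",
              x$C0, x$gamma, x$epsilon, carrying_capacity(x)))
  print(x$noise); invisible(x)
}

#' @export
print.coupled_model <- function(x, ...) {
  cat(sprintf("coupled growth-input model: C0 = %g, G0 = %g, gamma = %g, epsilon = %g\n",
              x$C0, x$G0, x$gamma, x$epsilon))
  print(x$noise); invisible(x)
}

## Default step: resolve the noise correlation time and the fastest
## deterministic time scale.
.default_dt <- function(noise, gamma = 0) {
  fast <- if (gamma > 0) min(1 / gamma, 1) else 1
  min(noise$tau_c / 10, 0.01 * fast)
}

## Internal integration grid: uniform refinement of [0, max(times)] that
## contains every requested output time.
.internal_grid <- function(times, dt) {
  tmax <- max(times)
  grid <- sort(unique(c(0, seq(0, tmax, by = dt), times, tmax)))
  grid[c(TRUE, diff(grid) > 1e-12)]
}

.default_cap <- function(model) {
  if (!is.null(model$epsilon) && model$epsilon > 0) 1e6 * carrying_capacity(model) else 1e6
}

.new_trajectory_ensemble <- function(times, values, model, seed, diverged,
                                     t_diverged, kind, extra = list()) {
  structure(c(list(times = times, values = values, params = model,
                   seed = as.integer(seed), diverged = diverged,
                   t_diverged = t_diverged, model = kind), extra),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf("%s-model trajectory ensemble: %d replicates x %d times on [%g, %g]\n",
              x$model, nrow(x$values), ncol(x$values), min(x$times), max(x$times)))
  nd <- sum(x$diverged)
  if (nd > 0) cat(sprintf("  %d replicate(s) flagged diverged (cap overflow)\n", nd))
  invisible(x)
}

## Cumulative trapezoid of each replicate's noise path (row-wise), used for
## the exact exponential-of-integral linear solution.
.cum_trapz <- function(g, dts) {
  n_t <- ncol(g)
  out <- matrix(0, nrow(g), n_t)
  for (j in seq_len(n_t - 1L))
    out[, j + 1L] <- out[, j] + 0.5 * dts[j] * (g[, j] + g[, j + 1L])
  out
}

#' Simulate the linear multiplicative-noise model
#'
#' Uses the exact exponential-of-integral solution
#' \eqn{C(t) = C_0 \exp(\gamma t + \Gamma(t))} with
#' \eqn{\Gamma(t) = \int_0^t g_c\,ds} accumulated by the trapezoid rule on
#' a fine internal grid, so there is no SDE-discretization bias: the only
#' error is the quadrature of the (exactly sampled) noise path.
#' Trajectories are strictly positive by construction.
#'
#' @param model a [linear_model()].
#' @param times requested output times (`>= 0`, strictly increasing).
#' @param n_reps ensemble size.
#' @param seed integer root seed (replicate streams are prefix-stable).
#' @param dt internal integration step; default
#'   `min(tau_c/10, 0.01 * min(1/gamma, 1))`.
#' @return A `trajectory_ensemble` with a replicate-by-time `values`
#'   matrix.
#' @export
simulate_linear <- function(model, times, n_reps, seed, dt = NULL) {
  stopifnot(inherits(model, "linear_model"))
  times <- .check_times(times)
  if (times[1] < 0) stop("`times` must be >= 0", call. = FALSE)
  if (is.null(dt)) dt <- .default_dt(model$noise, abs(model$gamma))
  grid <- .internal_grid(times, dt)
  idx <- match(round(times, 10), round(grid, 10))
  rep_seeds <- .replicate_seeds(seed, as.integer(n_reps))
  dts <- diff(grid)
  block <- max(1L, min(as.integer(n_reps), as.integer(2e7 / length(grid))))
  values <- matrix(0, n_reps, length(times))
  for (b in seq(1L, n_reps, by = block)) {
    rows <- b:min(b + block - 1L, n_reps)
    g <- .ou_paths(model$noise, grid, rep_seeds[rows])
    Gam <- .cum_trapz(g, dts)
    values[rows, ] <- model$C0 *
      exp(sweep(Gam[, idx, drop = FALSE], 2L, model$gamma * times, "+"))
  }
  .new_trajectory_ensemble(times, values, model, seed,
                           diverged = rep(FALSE, n_reps),
                           t_diverged = rep(NA_real_, n_reps), kind = "linear")
}

## One vectorized Heun step of dC/dt = gamma*C - (eps+g)*C^2 with noise
## values g0, g1 at the step endpoints.  Returns corrector and an O(h^2)
## error proxy (|corrector - predictor|).
.heun_step <- function(C, g0, g1, h, gamma, eps) {
  f0 <- gamma * C - (eps + g0) * C^2
  P <- C + h * f0
  f1 <- gamma * P - (eps + g1) * P^2
  C1 <- C + 0.5 * h * (f0 + f1)
  list(C = C1, err = abs(C1 - P))
}

## Scalar refinement by recursive step halving with linearly interpolated
## noise; returns the end value or NA once the state blows past `cap` or
## the step underflows.
.heun_refine <- function(C, g0, g1, h, gamma, eps, tol, cap, depth = 0L) {
  if (!is.finite(C) || C > cap || C <= 0) return(NA_real_)
  st <- .heun_step(C, g0, g1, h, gamma, eps)
  ok <- is.finite(st$C) && st$C > 0 && st$err <= tol * (abs(st$C) + 1)
  if (ok || depth >= 16L || h < 1e-12) {
    if (!ok && (depth >= 16L || h < 1e-12)) return(NA_real_)
    return(st$C)
  }
  gm <- 0.5 * (g0 + g1)
  Cm <- .heun_refine(C, g0, gm, h / 2, gamma, eps, tol, cap, depth + 1L)
  if (!is.finite(Cm) || Cm > cap) return(NA_real_)
  .heun_refine(Cm, gm, g1, h / 2, gamma, eps, tol, cap, depth + 1L)
}

#' Simulate the stochastic logistic self-regulation model
#'
#' Integrates \eqn{dC/dt = \gamma C - (\epsilon + g_c) C^2} along
#' exact-in-distribution colored-noise paths.  Two integrators are
#' provided:
#'
#' * `method = "heun"` (default): predictor-corrector stepping of the
#'   population equation with per-replicate recursive sub-stepping when
#'   the local step-error proxy exceeds `tol`.  Replicates whose
#'   population crosses `cap` (finite-time blow-up is possible whenever
#'   \eqn{\epsilon + g_c < 0} persists) are flagged diverged and frozen at
#'   the cap; they are reported, never dropped silently.
#' * `method = "inverse"`: exact second-order update of the inverse
#'   population \eqn{y = 1/C}, which obeys the *linear* equation
#'   \eqn{dy/dt = -\gamma y + \epsilon + g_c}.  This is the continuation
#'   of the flow through the blow-up (the population passes through
#'   infinity and can return); non-positive `y` at an output time is
#'   recorded as `NA` and flags the replicate, matching the truncation
#'   built into the analytic density.
#'
#' @inheritParams simulate_linear
#' @param model a [logistic_model()].
#' @param cap overflow threshold (default `1e6 * C_*`, or `1e6` when
#'   `epsilon = 0`); must exceed `C0`.
#' @param method `"heun"` or `"inverse"` (see Details).
#' @param tol relative local-error tolerance triggering sub-steps
#'   (Heun only).
#' @return A `trajectory_ensemble`; `diverged` and `t_diverged` record
#'   cap overflow (Heun) or an excursion through infinite population
#'   (inverse).
#' @export
simulate_logistic <- function(model, times, n_reps, seed, cap = NULL, dt = NULL,
                              method = c("heun", "inverse"), tol = 1e-3) {
  stopifnot(inherits(model, "logistic_model") || inherits(model, "coupled_model"))
  method <- match.arg(method)
  times <- .check_times(times)
  if (times[1] < 0) stop("`times` must be >= 0", call. = FALSE)
  if (is.null(cap)) cap <- .default_cap(model)
  if (cap <= model$C0) stop("`cap` must exceed `C0`", call. = FALSE)
  if (is.null(dt)) dt <- .default_dt(model$noise, model$gamma)
  grid <- .internal_grid(times, dt)
  idx <- match(round(times, 10), round(grid, 10))
  n_reps <- as.integer(n_reps)
  rep_seeds <- .replicate_seeds(seed, n_reps)
  dts <- diff(grid)
  gamma <- model$gamma; eps <- model$epsilon
  values <- matrix(NA_real_, n_reps, length(times))
  diverged <- rep(FALSE, n_reps)
  t_div <- rep(NA_real_, n_reps)
  block <- max(1L, min(n_reps, as.integer(2e7 / length(grid))))
  for (b in seq(1L, n_reps, by = block)) {
    rows <- b:min(b + block - 1L, n_reps)
    g <- .ou_paths(model$noise, grid, rep_seeds[rows])
    nb <- length(rows)
    if (method == "heun") {
      C <- rep(model$C0, nb)
      alive <- rep(TRUE, nb)
      if (1L %in% idx) values[rows, which(idx == 1L)] <- model$C0
      for (j in seq_along(dts)) {
        if (any(alive)) {
          h <- dts[j]
          st <- .heun_step(C[alive], g[alive, j], g[alive, j + 1L], h, gamma, eps)
          Cn <- st$C
          bad <- !is.finite(Cn) | Cn <= 0 | st$err > tol * (abs(Cn) + 1)
          if (any(bad)) {
            Cn[bad] <- vapply(which(bad), function(k) {
              i <- which(alive)[k]
              .heun_refine(C[i], g[i, j], g[i, j + 1L], h, gamma, eps, tol, cap)
            }, numeric(1))
          }
          newC <- C
          newC[alive] <- Cn
          died <- alive & (!is.finite(newC) | newC > cap)
          if (any(died)) {
            diverged[rows[died]] <- TRUE
            t_div[rows[died]] <- grid[j + 1L]
            newC[died] <- cap
            alive[died] <- FALSE
          }
          C <- newC
        }
        pos <- match(j + 1L, idx)
        if (!is.na(pos)) values[rows, pos] <- C
      }
    } else {
      y <- rep(1 / model$C0, nb)
      if (1L %in% idx) values[rows, which(idx == 1L)] <- model$C0
      for (j in seq_along(dts)) {
        h <- dts[j]
        a <- exp(-gamma * h)
        drift <- if (gamma != 0) (eps / gamma) * (1 - a) else eps * h
        y <- a * y + drift + 0.5 * h * (a * g[, j] + g[, j + 1L])
        crossed <- y <= 0
        if (any(crossed)) {
          first <- crossed & !diverged[rows]
          diverged[rows[first]] <- TRUE
          t_div[rows[first]] <- grid[j + 1L]
        }
        pos <- match(j + 1L, idx)
        if (!is.na(pos)) values[rows, pos] <- ifelse(y > 0, 1 / y, NA_real_)
      }
    }
  }
  .new_trajectory_ensemble(times, values, model, seed, diverged, t_div,
                           kind = "logistic", extra = list(cap = cap, method = method))
}

#' Simulate the coupled population / growth-input system
#'
#' Joint Heun integration of \eqn{dC/dt = G C} and
#' \eqn{dG/dt = \gamma - (\epsilon + g_c) C - G} along exact colored-noise
#' paths, with the same cap-and-flag divergence policy as
#' [simulate_logistic()].
#'
#' @inheritParams simulate_logistic
#' @param model a [coupled_model()].
#' @return A `trajectory_ensemble` whose `values` holds the population
#'   `C` and whose `growth_input` holds the matching `G` paths.
#' @export
simulate_coupled <- function(model, times, n_reps, seed, cap = NULL, dt = NULL) {
  stopifnot(inherits(model, "coupled_model"))
  times <- .check_times(times)
  if (times[1] < 0) stop("`times` must be >= 0", call. = FALSE)
  if (is.null(cap)) cap <- .default_cap(model)
  if (is.null(dt)) dt <- min(.default_dt(model$noise, model$gamma), 0.01)
  grid <- .internal_grid(times, dt)
  idx <- match(round(times, 10), round(grid, 10))
  n_reps <- as.integer(n_reps)
  rep_seeds <- .replicate_seeds(seed, n_reps)
  dts <- diff(grid)
  gamma <- model$gamma; eps <- model$epsilon
  values <- matrix(NA_real_, n_reps, length(times))
  Gout <- matrix(NA_real_, n_reps, length(times))
  diverged <- rep(FALSE, n_reps)
  t_div <- rep(NA_real_, n_reps)
  fC <- function(C, G) G * C
  fG <- function(C, G, g) gamma - (eps + g) * C - G
  block <- max(1L, min(n_reps, as.integer(1e7 / length(grid))))
  for (b in seq(1L, n_reps, by = block)) {
    rows <- b:min(b + block - 1L, n_reps)
    g <- .ou_paths(model$noise, grid, rep_seeds[rows])
    C <- rep(model$C0, length(rows))
    G <- rep(model$G0, length(rows))
    alive <- rep(TRUE, length(rows))
    if (1L %in% idx) {
      values[rows, which(idx == 1L)] <- C
      Gout[rows, which(idx == 1L)] <- G
    }
    for (j in seq_along(dts)) {
      h <- dts[j]
      kC1 <- fC(C, G); kG1 <- fG(C, G, g[, j])
      Cp <- C + h * kC1; Gp <- G + h * kG1
      kC2 <- fC(Cp, Gp); kG2 <- fG(Cp, Gp, g[, j + 1L])
      Cn <- C + 0.5 * h * (kC1 + kC2)
      Gn <- G + 0.5 * h * (kG1 + kG2)
      died <- alive & (!is.finite(Cn) | Cn > cap | Cn <= 0)
      if (any(died)) {
        diverged[rows[died]] <- TRUE
        t_div[rows[died]] <- grid[j + 1L]
        Cn[died] <- cap
        alive[died] <- FALSE
      }
      C <- ifelse(alive, Cn, C)
      G <- ifelse(alive, Gn, G)
      pos <- match(j + 1L, idx)
      if (!is.na(pos)) { values[rows, pos] <- C; Gout[rows, pos] <- G }
    }
  }
  .new_trajectory_ensemble(times, values, model, seed, diverged, t_div,
                           kind = "coupled",
                           extra = list(cap = cap, growth_input = Gout))
}

## Values usable for distributional summaries at output-time column `j`:
## finite, positive, below cap, and not from a replicate already diverged.
.usable_at <- function(ensemble, j) {
  x <- ensemble$values[, j]
  cap <- if (is.null(ensemble$cap)) Inf else ensemble$cap
  t <- ensemble$times[j]
  blocked <- ensemble$diverged & !is.na(ensemble$t_diverged) & ensemble$t_diverged <= t
  if (identical(ensemble$method, "inverse")) blocked <- rep(FALSE, length(x))
  ok <- is.finite(x) & x > 0 & x < cap & !blocked
  x[ok]
}

#' Empirical density histogram of an ensemble at one time point
#'
#' Diverged (or infinite-population, for the inverse integrator) replicates
#' are excluded and their count reported via the `excluded` attribute; the
#' returned density integrates to 1 over the binned support.
#'
#' @param ensemble a `trajectory_ensemble`.
#' @param t a time on the ensemble's output grid.
#' @param breaks passed to [graphics::hist()] semantics via
#'   [base::cut()]-style bin edges: either a bin count or a vector of
#'   edges.
#' @return data.frame with `bin_left`, `bin_right`, `density`;
#'   attributes `excluded` (replicate count) and `t`.
#' @export
ensemble_histogram <- function(ensemble, t, breaks = 50) {
  j <- which(abs(ensemble$times - t) <= 1e-9 * max(1, abs(t)))
  if (length(j) != 1L) stop("`t` is not on the ensemble time grid", call. = FALSE)
  x <- .usable_at(ensemble, j)
  if (length(x) == 0L) stop("all replicates diverged at the requested time", call. = FALSE)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  out <- data.frame(bin_left = utils::head(h$breaks, -1),
                    bin_right = utils::tail(h$breaks, -1),
                    density = h$density)
  attr(out, "excluded") <- nrow(ensemble$values) - length(x)
  attr(out, "t") <- t
  out
}
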