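#' Fitness functions over colony size
#'
#' A fitness function maps a population size to a survival probability
#' `f(C)` in `[0, 1]`.  Built-in shapes (all parameterized by a
#' `location` and `scale` on the population axis):
#'
#' * `"directed"`: increasing logistic sigmoid -- positive selection for
#'   large colonies.
#' * `"stabilizing"`: Gaussian bump centered at `location` -- selection
#'   toward an optimum size.
#' * `"therapeutic"`: decreasing sigmoid -- treatment that kills large
#'   colonies.
#' * `"uptake_threshold"`: decreasing sigmoid applied to the colony
#'   surface area \eqn{C^{2/3}} -- toxin uptake scales with surface area,
#'   so lethality switches on once \eqn{C^{2/3}} exceeds `location`.
#' * `"custom"`: two-column `table` (C, f) interpolated linearly and
#'   clamped to `[0, 1]`; constant extrapolation beyond the table range.
#'
#' @param kind one of the shapes above.
#' @param location center of the sigmoid / bump (on the `C` axis, or the
#'   \eqn{C^{2/3}} axis for `"uptake_threshold"`).
#' @param scale width of the transition, `> 0`.
#' @param table data.frame/matrix with columns `C`, `f` for
#'   `kind = "custom"`.
#' @return An object of class `fitness_function`; call it via `$fn(C)`.
#' @examples
#' f <- fitness_function("therapeutic", location = 2, scale = 0.5)
#' f$fn(c(0.5, 2, 8))
#' @export
fitness_function <- function(kind = c("directed", "stabilizing", "therapeutic",
                                      "uptake_threshold", "custom"),
                             location = 1, scale = 1, table = NULL) {
  kind <- match.arg(kind)
  if (kind != "custom" && (!is.numeric(scale) || scale <= 0))
    stop("`scale` must be > 0", call. = FALSE)
  fn <- switch(kind,
    directed = function(C) stats::plogis((C - location) / scale),
    stabilizing = function(C) exp(-(C - location)^2 / (2 * scale^2)),
    therapeutic = function(C) stats::plogis(-(C - location) / scale),
    uptake_threshold = function(C) stats::plogis(-(C^(2 / 3) - location) / scale),
    custom = {
      if (is.null(table)) stop("custom fitness needs a `table`", call. = FALSE)
      tab <- as.data.frame(table)
      names(tab)[1:2] <- c("C", "f")
      if (any(tab$f < 0 | tab$f > 1))
        stop("custom fitness values must lie in [0, 1]", call. = FALSE)
      af <- stats::approxfun(tab$C, tab$f, rule = 2)
      function(C) pmin(pmax(af(C), 0), 1)
    })
  structure(list(kind = kind, location = location, scale = scale,
                 table = if (kind == "custom") table else NULL, fn = fn),
            class = "fitness_function")
}

#' @export
print.fitness_function <- function(x, ...) {
  if (x$kind == "custom")
    cat(sprintf("custom tabulated fitness function (%d points)\n", nrow(x$table)))
  else
    cat(sprintf("%s fitness function: location = %g, scale = %g\n",
                x$kind, x$location, x$scale))
  invisible(x)
}

.density_fun <- function(density) {
  if (is.function(density)) return(density)
  tab <- as.data.frame(density)
  names(tab)[1:2] <- c("c", "p")
  af <- stats::approxfun(tab$c, tab$p, yleft = 0, yright = 0)
  function(c) pmax(af(c), 0)
}

#' Survivability coefficient under a fitness function
#'
#' The expected survivor fraction of a population distribution `P` under
#' fitness `f`,
#' \deqn{S = \int_0^\infty f(C)\,P(C)\,dC,}
#' together with the post-selection distribution \eqn{f P / S}.  The
#' input density must integrate to 1 within `norm_tol`.
#'
#' @param density a density function of `C`, or a two-column table
#'   `(C, p)` interpolated linearly.
#' @param f a [fitness_function()].
#' @param lower,upper integration support.
#' @param norm_tol allowed deviation of the density normalization from 1.
#' @return An object of class `survivability_result`: `S` in `[0, 1]`,
#'   `post_density` (function; `NULL` when `S = 0`), and the measured
#'   input `normalization`.
#' @export
survivability <- function(density, f, lower = 0, upper = Inf, norm_tol = 1e-3) {
  stopifnot(inherits(f, "fitness_function"))
  p <- .density_fun(density)
  norm <- stats::integrate(p, lower, upper, rel.tol = 1e-8,
                           subdivisions = 500L)$value
  if (abs(norm - 1) > norm_tol)
    stop(sprintf("density integrates to %.6g, not 1 (tolerance %g)", norm, norm_tol),
         call. = FALSE)
  S <- stats::integrate(function(c) f$fn(c) * p(c), lower, upper,
                        rel.tol = 1e-8, subdivisions = 500L)$value
  S <- min(max(S, 0), 1)
  post <- if (S > 0) {
    force(p); force(f)
    function(c) f$fn(c) * p(c) / S
  } else NULL
  structure(list(S = S, post_density = post, normalization = norm),
            class = "survivability_result")
}

#' @export
print.survivability_result <- function(x, ...) {
  cat(sprintf("survivability S = %.6g\n", x$S))
  invisible(x)
}

## Continue an ensemble of (population, noise-state) pairs for `duration`
## using one shared RNG stream.  The OU state persists across calls, so
## cellular memory carries over selection rounds.
.propagate_states <- function(model, C, g, duration, dt) {
  n <- length(C)
  grid <- seq(0, duration, by = dt)
  if (grid[length(grid)] < duration) grid <- c(grid, duration)
  dts <- diff(grid)
  noise <- model$noise
  a <- exp(-dts / noise$tau_c)
  b <- sqrt(noise$D * (1 - a^2))
  if (inherits(model, "linear_model")) {
    Gam <- numeric(n)
    for (j in seq_along(dts)) {
      gn <- a[j] * g + b[j] * stats::rnorm(n)
      Gam <- Gam + 0.5 * dts[j] * (g + gn)
      g <- gn
    }
    list(C = C * exp(model$gamma * duration + Gam), g = g,
         alive = rep(TRUE, n))
  } else {
    cap <- .default_cap(model)
    gamma <- model$gamma; eps <- model$epsilon
    alive <- rep(TRUE, n)
    for (j in seq_along(dts)) {
      gn <- a[j] * g + b[j] * stats::rnorm(n)
      st <- .heun_step(C, g, gn, dts[j], gamma, eps)
      Cn <- st$C
      bad <- alive & (!is.finite(Cn) | Cn <= 0 | Cn > cap)
      Cn[bad] <- NA_real_
      alive <- alive & !bad
      C <- ifelse(alive, Cn, C)
      g <- gn
    }
    list(C = C, g = g, alive = alive)
  }
}

#' Iterated selection sweeps on a simulated ensemble
#'
#' Repeats `n_rounds` of: regrow every surviving replicate for
#' `regrow_time` (colored-noise state and population state both persist
#' across rounds, so long correlation times keep colonies in their
#' pre-selection growth state), then apply the fitness function as an
#' instantaneous Bernoulli kill with survival probability `f(C)`.
#' Replicates of a logistic model that blow up during regrowth count as
#' killed.
#'
#' @param model a [linear_model()] or [logistic_model()].
#' @param f a [fitness_function()].
#' @param n_rounds number of selection rounds, `>= 1`.
#' @param regrow_time growth period before each selection event.
#' @param n_reps initial ensemble size.
#' @param seed integer seed (a single stream drives the whole experiment;
#'   identical seeds give identical round-by-round results).
#' @param dt internal integration step.
#' @return An object of class `selection_rounds`: per-round list with
#'   `round`, `n_before`, `n_survivors`, `survivor_fraction`, and
#'   survivor-state summaries (`mean_C`, `quartiles`).  Stops early (with
#'   the round recorded) if every replicate is killed.
#' @export
iterate_selection <- function(model, f, n_rounds, regrow_time, n_reps, seed,
                              dt = NULL) {
  stopifnot(inherits(f, "fitness_function"), n_rounds >= 1)
  if (is.null(dt)) dt <- .default_dt(model$noise, abs(model$gamma))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  C <- rep(model$C0, n_reps)
  g <- sqrt(model$noise$D) * stats::rnorm(n_reps)
  rounds <- list()
  for (r in seq_len(n_rounds)) {
    pr <- .propagate_states(model, C, g, regrow_time, dt)
    surv_prob <- ifelse(pr$alive, f$fn(pr$C), 0)
    survive <- stats::runif(length(C)) < surv_prob
    frac <- mean(survive)
    Cs <- pr$C[survive]
    rounds[[r]] <- list(round = r, n_before = length(C),
                        n_survivors = sum(survive), survivor_fraction = frac,
                        mean_C = if (any(survive)) mean(Cs) else NA_real_,
                        quartiles = if (any(survive))
                          stats::quantile(Cs, c(0.25, 0.5, 0.75)) else NULL)
    if (!any(survive)) {
      warning(sprintf("all replicates killed in round %d; stopping early", r),
              call. = FALSE)
      break
    }
    C <- Cs
    g <- pr$g[survive]
  }
  structure(list(rounds = rounds, n_rounds_requested = n_rounds,
                 regrow_time = regrow_time, seed = seed, model = model,
                 fitness = f),
            class = "selection_rounds")
}

#' @export
print.selection_rounds <- function(x, ...) {
  cat(sprintf("iterated selection: %d round(s), regrow_time = %g\n",
              length(x$rounds), x$regrow_time))
  for (r in x$rounds)
    cat(sprintf("  round %d: %d -> %d survivors (fraction %.4f)\n",
                r$round, r$n_before, r$n_survivors, r$survivor_fraction))
  invisible(x)
}

## S for one analytic density.  Linear: quadrature against the log-normal.
## Logistic: quadrature in the Gaussian z coordinates (f is bounded, so the
## integral converges on the full truncated support).
.analytic_S <- function(f, t_select, model, mode = "time_dependent") {
  if (inherits(model, "linear_model")) {
    s2 <- gamma_sq(t_select, model$noise)
    mu <- log(model$C0) + model$gamma * t_select
    stats::integrate(function(c) f$fn(c) * stats::dlnorm(c, mu, sqrt(s2)),
                     0, Inf, rel.tol = 1e-8, subdivisions = 1000L)$value
  } else {
    beta <- .beta_mode(t_select, model, mode)
    A <- logistic_A(t_select, model)
    N <- sqrt(beta / pi) / stats::pnorm(A * sqrt(2 * beta))
    sd <- 1 / sqrt(2 * beta)
    stats::integrate(function(z) N * exp(-beta * z^2) * f$fn(1 / (z + A)),
                     max(-A + 1e-12, -10 * sd), 10 * sd,
                     rel.tol = 1e-8, subdivisions = 1000L)$value
  }
}

#' Grid search for survivability-maximizing model parameters
#'
#' Evaluates the survivability coefficient `S` on an exhaustive parameter
#' grid using the analytic population densities (log-normal for the
#' linear model, reciprocal truncated Gaussian for the logistic model)
#' at selection time `t_select`, and ranks parameter sets by decreasing
#' `S`.  Deterministic: no simulation is involved.
#'
#' @param f a [fitness_function()].
#' @param t_select time of the selection event.
#' @param grid data.frame of parameter combinations; columns `D` and
#'   `tau_c` are required, `gamma` (default 0 for linear) and `epsilon`
#'   (logistic only) optional.  Build with [expand.grid()].
#' @param model `"linear"` or `"logistic"`.
#' @param C0 shared initial population.
#' @param mode beta convention for the logistic density.
#' @return the grid with an `S` column, sorted by decreasing `S`.
#' @export
optimize_survivability <- function(f, t_select, grid,
                                   model = c("linear", "logistic"), C0 = 1,
                                   mode = "time_dependent") {
  stopifnot(inherits(f, "fitness_function"), is.data.frame(grid), nrow(grid) > 0)
  model <- match.arg(model)
  if (!all(c("D", "tau_c") %in% names(grid)))
    stop("grid needs `D` and `tau_c` columns", call. = FALSE)
  S <- vapply(seq_len(nrow(grid)), function(i) {
    row <- grid[i, , drop = FALSE]
    m <- if (model == "linear") {
      linear_model(C0, gamma = if ("gamma" %in% names(row)) row$gamma else 0,
                   noise = noise_params(row$D, row$tau_c))
    } else {
      if (!all(c("gamma", "epsilon") %in% names(row)))
        stop("logistic grid needs `gamma` and `epsilon` columns", call. = FALSE)
      logistic_model(C0, gamma = row$gamma, epsilon = row$epsilon,
                     noise = noise_params(row$D, row$tau_c))
    }
    .analytic_S(f, t_select, m, mode)
  }, numeric(1))
  out <- grid
  out$S <- pmin(pmax(S, 0), 1)
  out[order(-out$S), , drop = FALSE]
}
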